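make_run <- function(targets, heads, seed = 3, plan = NULL, ...) {
  simulate_reaction_run(targets, heads, seed = seed, plan = plan, ...)
}

test_that("candidate extraction recovers exactly the planted MS2 scans", {
  st <- generate_heads_tails(4, 3)
  tg <- enumerate_conjugates(st$heads, st$tails)
  plan <- tibble::tibble(target_id = tg$target_id[1:3], adduct = "[M+H]+",
                         apex_height = c(5e5, 8e5, 3e5), n_ms2 = c(2L, 1L, 1L))
  sim <- make_run(tg, st$heads, seed = 9, plan = plan)
  cand <- extract_candidates(sim$run, tg, "[M+H]+")
  key <- function(d) paste(d$target_id, d$scan)
  expect_setequal(key(cand), key(sim$truth))
  # precursor offset far outside 10 ppm finds nothing
  run_off <- sim$run
  run_off$ms2 <- lapply(run_off$ms2, function(s) {
    s$precursor_mz <- s$precursor_mz * (1 + 25e-6); s
  })
  expect_identical(nrow(extract_candidates(run_off, tg, "[M+H]+")), 0L)
  # empty run is empty, not an error
  expect_identical(nrow(extract_candidates(list(file = "x", ms1 = list(),
                                                ms2 = list()), tg, "[M+H]+")), 0L)
})

test_that("intensity floors gate features as specified", {
  st <- generate_heads_tails(3, 2)
  tg <- enumerate_conjugates(st$heads, st$tails)
  plan <- tibble::tibble(target_id = tg$target_id[1:2], adduct = "[M+H]+",
                         apex_height = c(9e4, 5e5), n_ms2 = 1L)
  sim <- make_run(tg, st$heads, seed = 21, plan = plan)
  lib <- build_library(list(sim$run), tg, st$heads, adducts = "[M+H]+")
  ent <- lib$entries
  low <- ent[ent$target_id == tg$target_id[1], ]
  expect_true(all(!low$accepted))
  expect_true(all(low$first_fail == "feature_height"))
  expect_true(all(ent$accepted[ent$target_id == tg$target_id[2]]))
})

test_that("explanation score equals the exhaustive sub-formula oracle", {
  parent <- parse_formula("C6H11NO4")    # glycine C4:0 conjugate
  masses <- oracle_subformula_masses(parent)
  # every peak a protonated sub-formula -> 1; pure off-defect noise -> 0
  chem <- new_spectrum(sort(sample(masses[masses > 50], 5)), rep(10, 5),
                       precursor_mz = 162.08)
  expect_equal(ms2_explanation_score(chem, parent, 0.01), 1)
  noise <- new_spectrum(c(71.53, 95.47, 120.52), c(5, 5, 5), precursor_mz = 162.08)
  expect_equal(ms2_explanation_score(noise, parent, 0.01), 0)
  # half the intensity explained -> 0.5, and general agreement with the oracle
  half <- new_spectrum(c(sort(sample(masses[masses > 50], 2)), 101.46, 133.54),
                       c(10, 20, 15, 15), precursor_mz = 162.08)
  expect_equal(ms2_explanation_score(half, parent, 0.01), 0.5)
  set.seed(5)
  for (trial in 1:10) {
    sp <- new_spectrum(sort(stats::runif(8, 50, 160)), stats::runif(8, 1, 100),
                       precursor_mz = 162.08)
    expect_equal(ms2_explanation_score(sp, parent, 0.01),
                 oracle_explained_fraction(sp, parent, 0.01))
  }
  expect_warning(s0 <- ms2_explanation_score(
    new_spectrum(numeric(0), numeric(0), precursor_mz = 100), parent, 0.01),
    "empty")
  expect_identical(s0, 0)
})

test_that("diagnostic fragment curation follows the all-required policy", {
  glu <- fixture_heads()[3, ]   # curated fragments 84.04, 102.06, 130.05
  sp <- toy_spectrum(c(84.041, 102.055, 130.049, 250.1), c(50, 40, 60, 10))
  expect_true(diagnostic_fragment_check(sp, glu, frag_tol = 0.01))
  missing_one <- toy_spectrum(c(84.041, 102.055, 250.1), c(50, 40, 10))
  expect_false(diagnostic_fragment_check(missing_one, glu, frag_tol = 0.01))
  expect_true(diagnostic_fragment_check(missing_one, glu, frag_tol = 0.01,
                                        min_diag = 2))
  uncurated <- diagnostic_fragment_check(sp, fixture_heads()[1, ])
  expect_true(uncurated)
  expect_true(attr(uncurated, "uncurated"))
})

test_that("adduct inclusion anchors on [M+H]+ or [M+NH4]+", {
  ent <- tibble::tibble(
    target_id = c("T1", "T2", "T2", "T3", "T3"),
    adduct = c("[M+Na]+", "[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+"),
    accepted = TRUE)
  out <- apply_adduct_inclusion(ent)
  expect_identical(out$accepted, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  # anchors are never removed by this rule even when alone
  solo <- apply_adduct_inclusion(tibble::tibble(
    target_id = "T9", adduct = "[M+H]+", accepted = TRUE))
  expect_true(solo$accepted)
})

test_that("library audit conserves candidates and the build matches truth", {
  st <- generate_heads_tails(5, 3)
  tg <- enumerate_conjugates(st$heads, st$tails)
  sim <- make_run(tg, st$heads, seed = 17)
  lib <- build_library(list(sim$run), tg, st$heads)
  ent <- lib$entries
  expect_identical(sum(ent$accepted) + sum(!is.na(ent$first_fail)), nrow(ent))
  expect_true(all(is.na(ent$first_fail[ent$accepted])))
  aud <- lib$audit
  expect_equal(unname(aud$n[aud$gate == "candidates"]),
               sum(aud$n[aud$gate != "candidates"]))
  # all planted scans are accepted under default gates in this plan
  key <- function(d) paste(d$target_id, d$adduct, d$scan)
  expect_true(all(key(sim$truth) %in% key(ent[ent$accepted, ])))
  # impossible gate empties the library and the audit shows why
  lib2 <- build_library(list(sim$run), tg, st$heads,
                        gates = list(min_explanation = 1.1))
  expect_identical(sum(lib2$entries$accepted), 0L)
  expect_true(all(lib2$entries$first_fail == "explanation_score"))
})

test_that("loosening any gate never shrinks the accepted set", {
  st <- generate_heads_tails(4, 2)
  tg <- enumerate_conjugates(st$heads, st$tails)
  key <- function(lib) with(lib$entries[lib$entries$accepted, ],
                            paste(target_id, adduct, scan))
  for (seed in c(2, 23, 71)) {
    plan <- NULL
    sim <- simulate_reaction_run(tg, st$heads, seed = seed, detection_prob = 0.7)
    base <- build_library(list(sim$run), tg, st$heads)
    looser <- list(
      list(ppm_tol = 20), list(ms1_min = 1e4), list(height_min = 2e4),
      list(min_explanation = 0.3), list(min_diag = 1)
    )
    for (g in looser) {
      lib2 <- build_library(list(sim$run), tg, st$heads, gates = g)
      expect_true(all(key(base) %in% key(lib2)),
                  info = paste("seed", seed, names(g)))
    }
  }
})

test_that("library MGF and TSV exports round-trip the accepted entries", {
  st <- generate_heads_tails(3, 2)
  tg <- enumerate_conjugates(st$heads, st$tails)
  sim <- make_run(tg, st$heads, seed = 31)
  lib <- build_library(list(sim$run), tg, st$heads)
  mgf <- tempfile(fileext = ".mgf"); tsv <- tempfile(fileext = ".tsv")
  write_library_mgf(lib, tg, mgf)
  write_library_tsv(lib, tg, tsv)
  back <- read_mgf(mgf)
  expect_length(back, sum(lib$entries$accepted))
  acc <- lib$entries[lib$entries$accepted, ]
  expect_equal(back[[1]]$peaks[, "mz"], acc$spectrum[[1]]$peaks[, "mz"],
               tolerance = 1e-4)
  tab <- readr::read_tsv(tsv, col_types = readr::cols())
  expect_identical(nrow(tab), sum(lib$entries$accepted))
  expect_true(all(c("filename", "compound_name", "adduct", "smiles",
                    "exact_mass", "scan") %in% names(tab)))
  unlink(c(mgf, tsv))
})
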