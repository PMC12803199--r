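test_that("generators are byte-deterministic under a fixed seed", {
  st1 <- generate_heads_tails(6, 4, seed = 2)
  st2 <- generate_heads_tails(6, 4, seed = 2)
  expect_identical(st1, st2)
  tg <- enumerate_conjugates(st1$heads, st1$tails)
  s1 <- simulate_conjugate_spectrum(tg[1, ], st1$heads[1, ], seed = 8)
  s2 <- simulate_conjugate_spectrum(tg[1, ], st1$heads[1, ], seed = 8)
  expect_identical(s1$peaks, s2$peaks)
  r1 <- simulate_reaction_run(tg, st1$heads, seed = 8)
  r2 <- simulate_reaction_run(tg, st1$heads, seed = 8)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$run$ms2[[1]]$peaks, r2$run$ms2[[1]]$peaks)
  f1 <- simulate_feature_table(seed = 3); f2 <- simulate_feature_table(seed = 3)
  expect_identical(f1$table$areas, f2$table$areas)
})

test_that("head/tail generation emulates the study scale", {
  st <- generate_heads_tails(42, 19)
  expect_identical(nrow(st$heads), 42L)
  expect_identical(nrow(st$tails), 19L)
  expect_true(any(st$heads$n_primary_amines == 2))
  expect_true(all(lengths(st$heads$diagnostic_fragments) >= 2))
  expect_true(all(st$tails$carbons >= 3 & st$tails$carbons <= 18))
  dir <- tempfile(); st2 <- generate_heads_tails(5, 4, dir = dir)
  expect_identical(parse_head_table(file.path(dir, "heads.tsv"))$n_primary_amines,
                   st2$heads$n_primary_amines)
  expect_identical(parse_tail_table(file.path(dir, "tails.tsv"))$formula_str,
                   st2$tails$formula_str)
  unlink(dir, recursive = TRUE)
})

test_that("simulated spectra honor their recorded explained fraction", {
  st <- generate_heads_tails(4, 3)
  tg <- enumerate_conjugates(st$heads, st$tails)
  head2 <- st$heads[match(tg$head[2], st$heads$name), ]
  noise_off <- list(mz_sd = 0.0005, int_sigma = 0.3, n_spurious = 0L)
  clean <- simulate_conjugate_spectrum(tg[2, ], head2, noise = noise_off,
                                       seed = 4)
  expect_identical(attr(clean, "truth")$explained_fraction, 1)
  expect_gte(ms2_explanation_score(clean, tg$formula[[2]], 0.01), 0.99)
  # heavy spurious load drives the planted fraction (and the score) down
  dirty_noise <- list(mz_sd = 0.0005, int_sigma = 0.3, n_spurious = 40L,
                      spurious_meanlog = log(5e3))
  dirty <- simulate_conjugate_spectrum(tg[2, ], head2, noise = dirty_noise,
                                       seed = 4)
  expect_lt(attr(dirty, "truth")$explained_fraction, 0.6)
  expect_lt(ms2_explanation_score(dirty, tg$formula[[2]], 0.01), 0.8)
})

test_that("repository construction meets its planted and decoy guarantees", {
  st <- generate_heads_tails(4, 3)
  tg <- enumerate_conjugates(st$heads, st$tails)
  sim <- simulate_reaction_run(tg, st$heads, seed = 6)
  lib <- build_library(list(sim$run), tg, st$heads)
  lq <- library_query_table(lib)
  repo <- simulate_repository(lq, sim_config(seed = 6, corpus = list(n_files = 12)),
                              seed = 7)
  # planted copies keep cosine >= 0.9 against their originals
  for (k in seq_len(nrow(repo$truth))) {
    orig <- lq$spectrum[[match(repo$truth$query_id[k], lq$query_id)]]
    copy <- repo$corpus$spectrum[[which(
      repo$corpus$corpus_file == repo$truth$corpus_file[k] &
        repo$corpus$scan == repo$truth$scan[k])]]
    expect_gte(raw_cosine(copy, orig, 0.02)$cosine, 0.9)
  }
  # decoy spectra share fewer than 3 coincident ions with any library spectrum
  decoy_files <- setdiff(repo$corpus$corpus_file,
                         c(repo$truth$corpus_file,
                           repo$metadata$file_id[repo$metadata$sample_role == "blank"]))
  for (f in decoy_files) {
    for (sp in repo$corpus$spectrum[repo$corpus$corpus_file == f]) {
      worst <- max(vapply(lq$spectrum, function(ls) {
        sum(vapply(sp$peaks[, "mz"],
                   function(m) any(abs(ls$peaks[, "mz"] - m) <= 0.02), logical(1)))
      }, numeric(1)))
      expect_lt(worst, 3)
    }
  }
  # every file has metadata
  expect_true(all(repo$corpus$corpus_file %in% repo$metadata$file_id))
})

test_that("null feature tables produce a near-nominal significant fraction", {
  cfg <- sim_config(seed = 14, effects = list(n_features = 800, n_affected = 0,
                                              n_contaminants = 0))
  sim <- simulate_feature_table(cfg, seed = 14)
  res <- group_compare(sim$table, c("case", "control"))
  frac <- mean(res$significant)
  expect_gt(frac, 0.02); expect_lt(frac, 0.08)
})
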