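small_search_world <- function(seed = 5, n_files = 10) {
  st <- generate_heads_tails(5, 3)
  tg <- enumerate_conjugates(st$heads, st$tails)
  sim <- simulate_reaction_run(tg, st$heads, seed = seed)
  lib <- build_library(list(sim$run), tg, st$heads)
  lq <- library_query_table(lib)
  repo <- simulate_repository(lq, sim_config(seed = seed,
                                             corpus = list(n_files = n_files)),
                              seed = seed + 1)
  list(lq = lq, repo = repo)
}

test_that("indexed search equals the all-pairs scan and honors its gates", {
  w <- small_search_world(seed = 5)
  m_idx <- fasst_search(w$lq, w$repo$corpus, index = TRUE)
  m_all <- fasst_search(w$lq, w$repo$corpus, index = FALSE)
  key <- function(d) paste(d$query_id, d$corpus_file, d$scan)
  expect_setequal(key(m_idx), key(m_all))
  expect_true(all(m_idx$cosine >= 0.7))
  expect_true(all(m_idx$n_matched >= 3))
  expect_true(all(abs(m_idx$precursor_delta) <= 0.02))
  # recall 1.0 on planted copies; decoy files stay silent
  expect_true(all(key(w$repo$truth) %in% key(m_idx)))
  decoys <- setdiff(w$repo$corpus$corpus_file, w$repo$truth$corpus_file)
  expect_identical(sum(m_idx$corpus_file %in% decoys), 0L)
  # empty corpus
  empty <- w$repo$corpus[0, ]
  expect_identical(nrow(fasst_search(w$lq, empty)), 0L)
})

test_that("lowering the cosine or matched-ion gate never removes a match", {
  w <- small_search_world(seed = 8)
  key <- function(d) paste(d$query_id, d$corpus_file, d$scan)
  base <- fasst_search(w$lq, w$repo$corpus, min_cos = 0.7, min_matched = 3)
  lower_cos <- fasst_search(w$lq, w$repo$corpus, min_cos = 0.5, min_matched = 3)
  lower_ions <- fasst_search(w$lq, w$repo$corpus, min_cos = 0.7, min_matched = 2)
  expect_true(all(key(base) %in% key(lower_cos)))
  expect_true(all(key(base) %in% key(lower_ions)))
  # raising min_matched beyond the richest spectrum empties the result
  max_peaks <- max(vapply(w$lq$spectrum, n_peaks, integer(1)))
  expect_identical(nrow(fasst_search(w$lq, w$repo$corpus,
                                     min_matched = max_peaks + 1L)), 0L)
})

test_that("molecular networks link homologs with the expected delta mass", {
  st <- generate_heads_tails(8, 6)
  glu <- st$heads[st$heads$name == "glutamic acid", ]
  tails <- tails_from_rows(tail_name(c(12, 14), c(0, 0)),
                           vapply(c(12, 14), hydroxy_tail_smiles, character(1)))
  tg <- enumerate_conjugates(glu, tails)
  noise_off <- list(mz_sd = 0.0005, int_sigma = 0.2, n_spurious = 0L)
  s12 <- simulate_conjugate_spectrum(tg[1, ], glu, noise = noise_off, seed = 1, rt = 4.0)
  s14 <- simulate_conjugate_spectrum(tg[2, ], glu, noise = noise_off, seed = 2, rt = 5.1)
  feats <- tibble::tibble(feature_id = c("F1", "F2"), spectrum = list(s12, s14))
  edges <- build_network(feats, min_cos = 0.7, min_matched = 2)
  expect_identical(nrow(edges), 1L)
  expect_equal(abs(edges$delta_mass), 28.0313, tolerance = 0.01)
  # identical features give a single cosine-1 edge with zero delta
  twin <- tibble::tibble(feature_id = c("A", "B"), spectrum = list(s12, s12))
  e2 <- build_network(twin)
  expect_identical(nrow(e2), 1L)
  expect_equal(e2$cosine, 1, tolerance = 1e-12)
  expect_identical(e2$delta_mass, 0)
  # all-noise features stay unconnected at default gates
  set.seed(99)
  noisy <- tibble::tibble(
    feature_id = paste0("N", 1:4),
    spectrum = lapply(1:4, function(i) revamide:::.noise_spectrum(300 + i * 0.001)))
  expect_identical(nrow(build_network(noisy)), 0L)
})

test_that("annotation propagation follows homolog deltas and the RT rule", {
  mk <- function(id, prec, rt) tibble::tibble(feature_id = id, precursor_mz = prec, rt = rt)
  feats <- dplyr::bind_rows(mk("seed", 290.16, 4.0), mk("up", 290.16 + 28.0313, 5.0),
                            mk("down_bad_rt", 290.16 + 28.0313, 2.0),
                            mk("unrelated", 353.9, 4.2))
  edges <- tibble::tibble(
    feature_a = c("seed", "seed", "seed"),
    feature_b = c("up", "down_bad_rt", "unrelated"),
    cosine = 0.9, delta_mass = c(-28.0313, -28.0313, -63.74), n_matched = 4L)
  seeds <- tibble::tibble(feature_id = "seed", head = "glutamic acid",
                          carbons = 12L, unsaturations = 0L)
  ann <- propagate_annotations(edges, feats, seeds)
  expect_identical(ann$feature_id, "up")
  expect_identical(ann$annotation, "glutamic acid 3OH-C14:0")
  expect_identical(ann$msi_level, 2L)
  expect_true(all(ann$putative))
  # no seeds, no propagation
  expect_identical(nrow(propagate_annotations(edges, feats, seeds[0, ])), 0L)
})

test_that("network GraphML export is readable by igraph", {
  st <- generate_heads_tails(3, 2)
  tg <- enumerate_conjugates(st$heads[1, ], st$tails)
  glu <- st$heads[1, ]
  sps <- lapply(1:2, function(i) simulate_conjugate_spectrum(
    tg[i, ], glu, seed = i, rt = i,
    noise = list(mz_sd = 0.001, int_sigma = 0.2, n_spurious = 0L)))
  feats <- tibble::tibble(feature_id = c("F1", "F2"), spectrum = sps)
  edges <- build_network(feats, min_cos = 0.2, min_matched = 1)
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(edges, path, features = feats)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), nrow(edges))
  unlink(path)
})
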