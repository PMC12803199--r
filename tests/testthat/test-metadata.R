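test_that("metadata joins keep every match and label the unknown", {
  md <- tibble::tibble(
    file_id = c("a.mzML", "b.mzML"),
    taxonomy = c("9606|Homo sapiens", "10090|Mus musculus"),
    body_part = c("feces", "blood"), disease = c("healthy", "missing"),
    sample_role = "sample")
  matches <- tibble::tibble(
    query_id = "Q1", corpus_file = c("a", "b", "mystery"),
    scan = 1:3, cosine = 0.9, n_matched = 5L, precursor_delta = 0)
  out <- join_matches(matches, md)
  expect_identical(nrow(out), 3L)
  expect_identical(out$taxonomy, c("9606|Homo sapiens", "10090|Mus musculus",
                                   "unannotated"))
  # empty metadata -> everything unannotated, nothing dropped
  all_un <- join_matches(matches, md[0, ])
  expect_identical(all_un$body_part, rep("unannotated", 3))
  expect_error(join_matches(matches, dplyr::bind_rows(md, md[1, ])), "duplicate")
})

test_that("ReDU-style TSVs read with explicit missing markers", {
  tf <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    filename = c("f1", "f2"), NCBITaxonomy = c("9606|Homo sapiens", NA),
    UBERONBodyPartName = c("skin", ""), DOIDCommonName = NA,
    SampleType = c("sample", "blank")), tf)
  md <- read_sample_metadata(tf)
  expect_identical(md$taxonomy[2], "missing")
  expect_identical(md$body_part[2], "missing")
  expect_identical(md$disease, c("missing", "missing"))
  expect_identical(md$sample_role, c("sample", "blank"))
  unlink(tf)
})

test_that("presence matrix distinguishes no-spectrum from no-match cells", {
  lib <- tibble::tibble(head = c("glycine", "glycine"), tail = c("3OH-C4:0", "3OH-C12:0"))
  empty_matches <- tibble::tibble(
    query_id = character(0), corpus_file = character(0), scan = integer(0),
    cosine = numeric(0), n_matched = integer(0), precursor_delta = numeric(0),
    head = character(0), tail = character(0), taxonomy = character(0),
    body_part = character(0), disease = character(0), sample_role = character(0))
  rep0 <- presence_and_counts(empty_matches, lib,
                              grid_heads = c("glycine", "ornithine"),
                              grid_tails = c("3OH-C4:0", "3OH-C12:0"))
  expect_identical(unname(rep0$presence["glycine", ]), c("no_match", "no_match"))
  expect_identical(unname(rep0$presence["ornithine", ]), rep("no_spectrum", 2))
  expect_identical(unname(rep0$counts["glycine", ]), c(0, 0))
  expect_true(all(is.na(rep0$counts["ornithine", ])))
  one <- empty_matches
  one[1, ] <- list("Q1", "fileX", 1L, 0.9, 4L, 0.001, "glycine", "3OH-C4:0",
                   "9606|Homo sapiens", "feces", "healthy", "sample")
  rep1 <- presence_and_counts(one, lib)
  expect_identical(rep1$presence["glycine", "3OH-C4:0"], "matched")
  expect_identical(rep1$counts["glycine", "3OH-C4:0"], 1)
  expect_identical(rep1$by_body_part$n_files, 1L)
  # matched cells always carry a count of at least one
  expect_true(all(rep1$counts[rep1$presence == "matched"] >= 1))
})

test_that("per-group tallies equal the generator's planted histogram", {
  st <- generate_heads_tails(5, 3)
  tg <- enumerate_conjugates(st$heads, st$tails)
  sim <- simulate_reaction_run(tg, st$heads, seed = 12)
  lib <- build_library(list(sim$run), tg, st$heads)
  lq <- library_query_table(lib)
  repo <- simulate_repository(lq, sim_config(seed = 12, corpus = list(n_files = 14)),
                              seed = 13)
  m <- fasst_search(lq, repo$corpus)
  ann <- join_matches(
    dplyr::left_join(m, lq[, c("query_id", "head", "tail")], by = "query_id"),
    repo$metadata)
  got <- presence_and_counts(ann, lq)$by_body_part
  want <- dplyr::count(repo$truth, group = body_part)
  # every planted organ is recovered with at least its planted count
  for (k in seq_len(nrow(want))) {
    g <- got[got$group == want$group[k], ]
    expect_identical(nrow(g), 1L)
    expect_gte(g$n_matches, want$n[k])
  }
  # and every annotated match is accounted for (join conservation)
  expect_identical(sum(got$n_matches), nrow(m))
})

test_that("chain-class summaries partition matches and round percentages", {
  ann <- tibble::tibble(tail = c(rep("3OH-C3:0", 5), rep("3OH-C5:0", 3),
                                 rep("3OH-C4:0", 4), "weird"))
  cs <- chain_class_summary(ann)
  expect_identical(sum(cs$by_parity$n_matches), nrow(ann))
  odd <- cs$by_tail[cs$by_tail$parity == "odd", ]
  expect_identical(sum(odd$n_matches), 8L)
  expect_identical(odd$pct_within_parity[odd$tail == "3OH-C3:0"], 63)  # 5/8
  expect_identical(cs$by_parity$n_matches[cs$by_parity$parity == "unknown"], 1L)
  # all matches on one even tail
  cs2 <- chain_class_summary(tibble::tibble(tail = rep("3OH-C12:0", 7)))
  expect_identical(cs2$by_parity$parity, "even")
  expect_identical(cs2$by_tail$pct_within_parity, 100)
  # rounding is half-away-from-zero
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(-0.5), -1)
  expect_identical(pct_of(1, 8), 13)
})

test_that("bundled reported-count tables load", {
  ad <- reported_counts("library_adducts")
  expect_identical(nrow(ad), 5L)
  expect_true(all(c("adduct", "n_spectra") %in% names(ad)))
  rf <- reported_counts("repository_files")
  expect_identical(nrow(rf), 3L)
})
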