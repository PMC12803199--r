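# Joining spectral matches to harmonized sample metadata and the
# aggregation surfaces built on top: per-group tallies, head x tail
# presence/count matrices, and chain-class summaries.

#' Read a ReDU-style sample metadata table
#'
#' Expects TSV columns `filename`, `NCBITaxonomy`,
#' `UBERONBodyPartName`, `DOIDCommonName`, `SampleType`. Unknown or
#' empty fields become the explicit string `"missing"`; rows are never
#' dropped.
#'
#' @param path TSV path.
#' @return A tibble: `file_id`, `taxonomy`, `body_part`, `disease`,
#'   `sample_role`.
#' @export
read_sample_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("filename", "NCBITaxonomy", "UBERONBodyPartName", "DOIDCommonName", "SampleType")
  missing_cols <- setdiff(need, names(raw))
  for (mc in missing_cols) raw[[mc]] <- NA_character_
  fill <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), "missing", x)
  tibble::tibble(
    file_id = raw$filename,
    taxonomy = fill(raw$NCBITaxonomy),
    body_part = fill(raw$UBERONBodyPartName),
    disease = fill(raw$DOIDCommonName),
    sample_role = ifelse(is.na(raw$SampleType), "sample", tolower(raw$SampleType))
  )
}

.normalize_file_id <- function(x) {
  sub("\\.(mzML|mzXML|mgf|raw|d)$", "", basename(trimws(x)), ignore.case = TRUE)
}

#' Join spectral matches to sample metadata
#'
#' File identifiers are normalized (directory and extension stripped)
#' before the exact join. Matches to files absent from the metadata
#' are kept and labeled `"unannotated"`; no match is ever discarded.
#'
#' @param matches Match tibble from [fasst_search()].
#' @param metadata Metadata tibble from [read_sample_metadata()].
#' @return The match tibble with `taxonomy`, `body_part`, `disease`,
#'   `sample_role` columns added.
#' @export
join_matches <- function(matches, metadata) {
  md <- metadata
  md$.file_key <- .normalize_file_id(md$file_id)
  dup <- unique(md$.file_key[duplicated(md$.file_key)])
  if (length(dup) > 0) {
    stop("duplicate file_id in metadata: ", paste(dup, collapse = ", "))
  }
  out <- matches
  out$.file_key <- .normalize_file_id(out$corpus_file)
  out <- dplyr::left_join(out, md[, c(".file_key", "taxonomy", "body_part",
                                      "disease", "sample_role")],
                          by = ".file_key")
  for (col in c("taxonomy", "body_part", "disease", "sample_role")) {
    out[[col]][is.na(out[[col]])] <- "unannotated"
  }
  out$.file_key <- NULL
  out
}

#' Round half away from zero
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded values; `round_half_up(0.5)` is 1.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a part within a whole, integer-rounded
#' @param part,whole Numeric.
#' @return `round_half_up(100 * part / whole)`.
#' @export
pct_of <- function(part, whole) {
  round_half_up(100 * part / whole)
}

#' Presence and count matrices over the head x tail grid
#'
#' Builds the three-state presence matrix (a head x tail cell is
#' `"no_spectrum"` when the library holds no spectrum for the pair,
#' `"no_match"` when a spectrum exists but found nothing, `"matched"`
#' otherwise), the match-count matrix, and per-group tally tables.
#' Unique-compound counting collapses adducts and isomers of the same
#' head x tail pair.
#'
#' @param annotated Annotated match tibble from [join_matches()]; must
#'   carry `head` and `tail` columns (join the query table if needed).
#' @param library_compounds Tibble with `head` and `tail` columns
#'   listing the pairs that have library spectra.
#' @param grid_heads,grid_tails Optional full axes of the grid
#'   (default: those occurring in `library_compounds`).
#' @return A list of class `aggregation_report`: `presence`
#'   (character matrix), `counts` (numeric matrix), `by_taxonomy`,
#'   `by_body_part`, `by_disease` (tibbles with `n_matches`,
#'   `n_unique_compounds`, `n_files`).
#' @export
presence_and_counts <- function(annotated, library_compounds,
                                grid_heads = NULL, grid_tails = NULL) {
  lib <- unique(library_compounds[, c("head", "tail")])
  heads <- if (is.null(grid_heads)) sort(unique(lib$head)) else grid_heads
  tails <- if (is.null(grid_tails)) unique(lib$tail) else grid_tails
  presence <- matrix("no_spectrum", length(heads), length(tails),
                     dimnames = list(heads, tails))
  counts <- matrix(NA_real_, length(heads), length(tails),
                   dimnames = list(heads, tails))
  for (k in seq_len(nrow(lib))) {
    if (lib$head[k] %in% heads && lib$tail[k] %in% tails) {
      presence[lib$head[k], lib$tail[k]] <- "no_match"
      counts[lib$head[k], lib$tail[k]] <- 0
    }
  }
  if (nrow(annotated) > 0) {
    tal <- dplyr::count(annotated, .data$head, .data$tail)
    for (k in seq_len(nrow(tal))) {
      h <- tal$head[k]; t <- tal$tail[k]
      if (h %in% heads && t %in% tails && presence[h, t] != "no_spectrum") {
        presence[h, t] <- "matched"
        counts[h, t] <- tal$n[k]
      }
    }
  }
  group_tab <- function(col) {
    if (nrow(annotated) == 0) {
      return(tibble::tibble(group = character(0), n_matches = integer(0),
                            n_unique_compounds = integer(0), n_files = integer(0)))
    }
    annotated |>
      dplyr::group_by(group = .data[[col]]) |>
      dplyr::summarise(
        n_matches = dplyr::n(),
        n_unique_compounds = dplyr::n_distinct(paste(.data$head, .data$tail)),
        n_files = dplyr::n_distinct(.data$corpus_file),
        .groups = "drop"
      )
  }
  structure(list(
    presence = presence, counts = counts,
    by_taxonomy = group_tab("taxonomy"),
    by_body_part = group_tab("body_part"),
    by_disease = group_tab("disease")
  ), class = "aggregation_report")
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat(sprintf("<aggregation_report: %d x %d head x tail grid; %d matched cells>\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence == "matched")))
  invisible(x)
}

#' Chain parity and saturation summary of annotated matches
#'
#' Partitions matches by the parity (odd/even carbon count) and
#' saturation of the lipid tail, and reports each tail's share of its
#' parity class as an integer percentage (rounded half away from
#' zero). Matches whose tail name cannot be parsed are tallied under
#' `"unknown"`, never dropped.
#'
#' @param annotated Match tibble carrying a `tail` column with
#'   `3OH-Cn:m` names.
#' @return A list: `by_parity` (odd/even/unknown counts),
#'   `by_saturation` (saturated/unsaturated counts), `by_tail`
#'   (per-tail counts with `pct_within_parity`).
#' @export
chain_class_summary <- function(annotated) {
  n <- nrow(annotated)
  parsed <- tryCatch(parse_tail_name(annotated$tail), error = function(e) NULL)
  if (is.null(parsed)) {
    ok <- grepl("^3OH-C[0-9]+:[0-9]+$", annotated$tail)
    parsed <- tibble::tibble(carbons = rep(NA_integer_, n),
                             unsaturations = rep(NA_integer_, n))
    if (any(ok)) parsed[ok, ] <- parse_tail_name(annotated$tail[ok])
  }
  cls <- tibble::tibble(
    tail = annotated$tail,
    parity = dplyr::case_when(
      is.na(parsed$carbons) ~ "unknown",
      parsed$carbons %% 2 == 1 ~ "odd",
      TRUE ~ "even"
    ),
    saturation = dplyr::case_when(
      is.na(parsed$unsaturations) ~ "unknown",
      parsed$unsaturations == 0 ~ "saturated",
      TRUE ~ "unsaturated"
    )
  )
  by_parity <- dplyr::count(cls, .data$parity, name = "n_matches")
  by_sat <- dplyr::count(cls, .data$saturation, name = "n_matches")
  by_tail <- cls |>
    dplyr::count(.data$parity, .data$tail, name = "n_matches") |>
    dplyr::group_by(.data$parity) |>
    dplyr::mutate(pct_within_parity = pct_of(.data$n_matches, sum(.data$n_matches))) |>
    dplyr::ungroup()
  list(by_parity = by_parity, by_saturation = by_sat, by_tail = by_tail)
}

#' Reported repository-search summary counts
#'
#' Loads the published summary tables distributed with the package
#' (adduct distribution of the 3-HYDROXY-ACYL-AMIDES-LIBRARY deposit,
#' per-repository unique-file counts, and chain-class match counts
#' from the repository-scale search). These are inputs for
#' bookkeeping checks, not quantities the package computes.
#'
#' @param which One of `"library_adducts"`, `"repository_files"`,
#'   `"chain_matches"`.
#' @return A tibble.
#' @export
reported_counts <- function(which = c("library_adducts", "repository_files",
                                      "chain_matches")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reported_counts", paste0(which, ".tsv"),
                      package = "revamide", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols())
}
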