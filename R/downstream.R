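# Feature-table statistics: blank filtering, two-group comparisons,
# time trends, and MSI confidence assignment.

#' Construct a feature table
#'
#' @param features Tibble with `feature_id`, `mz`, `rt` and optionally
#'   `drift`.
#' @param samples Tibble with `sample_id`, `group`, `role` (one of
#'   `sample`, `blank`, `control`).
#' @param areas Numeric matrix of peak areas, features x samples
#'   (non-negative), with dimnames matching the id columns.
#' @return A list of class `feature_table`.
#' @export
feature_table <- function(features, samples, areas) {
  stopifnot(nrow(areas) == nrow(features), ncol(areas) == nrow(samples))
  if (any(areas < 0)) stop("negative peak areas")
  dimnames(areas) <- list(features$feature_id, samples$sample_id)
  structure(list(features = features, samples = samples, areas = areas),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d features x %d samples (%d blanks)>\n",
              nrow(x$features), nrow(x$samples), sum(x$samples$role == "blank")))
  invisible(x)
}

#' Read a feature table from feature-finder CSV export
#'
#' Expects columns `feature_id`, `mz`, `rt`, optional `drift`, then
#' one `area_<sample>` column per sample; sample group and role come
#' from a companion tibble.
#'
#' @param path CSV path.
#' @param samples Tibble with `sample_id`, `group`, `role`.
#' @return A `feature_table`.
#' @export
read_feature_csv <- function(path, samples) {
  raw <- readr::read_csv(path, col_types = readr::cols())
  area_cols <- paste0("area_", samples$sample_id)
  missing <- setdiff(area_cols, names(raw))
  if (length(missing) > 0) stop("missing area columns: ", paste(missing, collapse = ", "))
  feats <- raw[, intersect(c("feature_id", "mz", "rt", "drift"), names(raw))]
  feature_table(feats, samples, as.matrix(raw[, area_cols]))
}

#' Write a feature table to CSV
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  areas <- table$areas
  colnames(areas) <- paste0("area_", colnames(areas))
  readr::write_csv(dplyr::bind_cols(table$features, tibble::as_tibble(areas)), path)
  invisible(path)
}

#' Blank filtering of a feature table
#'
#' A feature is retained when its mean area across biological samples
#' is at least `ratio_min` times its mean area across blanks (with a
#' small floor `eps` guarding empty blanks). Removed features are
#' listed in the `audit` attribute.
#'
#' @param table A `feature_table` containing at least one blank.
#' @param ratio_min Sample/blank mean-ratio threshold (default 3, a
#'   common contamination cut).
#' @param eps Floor for the blank mean (default 1 area unit).
#' @return The filtered `feature_table`; attribute `audit` is a
#'   tibble of removed features with their ratios.
#' @export
blank_filter <- function(table, ratio_min = 3, eps = 1) {
  roles <- table$samples$role
  if (!any(roles == "blank")) {
    stop("no blank samples in the table; skip the blank filter explicitly ",
         "if this is intended")
  }
  smp <- roles == "sample"
  blk <- roles == "blank"
  mean_s <- rowMeans(table$areas[, smp, drop = FALSE])
  mean_b <- rowMeans(table$areas[, blk, drop = FALSE])
  ratio <- mean_s / pmax(mean_b, eps)
  keep <- ratio >= ratio_min
  audit <- tibble::tibble(feature_id = table$features$feature_id[!keep],
                          mean_sample = mean_s[!keep], mean_blank = mean_b[!keep],
                          ratio = ratio[!keep])
  out <- feature_table(table$features[keep, , drop = FALSE], table$samples,
                       table$areas[keep, , drop = FALSE])
  attr(out, "audit") <- audit
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration (via the null rank-sum distribution) when the
#' smaller group has at most 8 observations and there are no ties;
#' normal approximation with tie and continuity correction otherwise.
#' Identical values across both groups give p = 1 with a warning.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return A list with `statistic` (Mann-Whitney W for `x`) and
#'   `p_value` in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(w$statistic), p_value = min(w$p.value, 1))
}

#' Per-feature two-group comparison
#'
#' Wilcoxon rank-sum per feature between two sample groups (blanks
#' and controls excluded), with log10 fold change computed on
#' `eps`-stabilized group means. Raw p-values are compared against
#' `alpha` by default; Benjamini-Hochberg adjustment is available via
#' `p_adjust = "BH"`.
#'
#' @param table A `feature_table`.
#' @param groups Character vector of two group labels, fold change is
#'   `log10(mean(groups[1]) / mean(groups[2]))`.
#' @param alpha Significance level (default 0.05).
#' @param eps Mean stabilizer in the fold change (default 1 area unit).
#' @param p_adjust `"none"` (default) or any method of
#'   [stats::p.adjust()].
#' @return A tibble: `feature_id`, `mean_a`, `mean_b`, `log10_fc`,
#'   `statistic`, `p_value`, `p_used`, `significant`.
#' @export
group_compare <- function(table, groups, alpha = 0.05, eps = 1,
                          p_adjust = "none") {
  stopifnot(length(groups) == 2)
  s <- table$samples
  ia <- which(s$group == groups[1] & s$role == "sample")
  ib <- which(s$group == groups[2] & s$role == "sample")
  if (length(ia) == 0 || length(ib) == 0) {
    stop("group label(s) not found among samples; available: ",
         paste(unique(s$group[s$role == "sample"]), collapse = ", "))
  }
  res <- lapply(seq_len(nrow(table$features)), function(f) {
    a <- table$areas[f, ia]; b <- table$areas[f, ib]
    w <- suppressWarnings(wilcoxon_rank_sum(a, b))
    tibble::tibble(
      feature_id = table$features$feature_id[f],
      mean_a = mean(a), mean_b = mean(b),
      log10_fc = log10((mean(a) + eps) / (mean(b) + eps)),
      statistic = w$statistic, p_value = w$p_value
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_used <- if (p_adjust == "none") out$p_value else stats::p.adjust(out$p_value, p_adjust)
  out$significant <- out$p_used < alpha
  out
}

#' First-vs-last-bin trend check with rank correlation
#'
#' For longitudinal series (e.g. abundance over decomposition time):
#' a Wilcoxon rank-sum between the first and last time bins, plus a
#' Spearman rank correlation of abundance against time. Both verdicts
#' are reported; neither is folded into the other.
#'
#' @param values Numeric abundances.
#' @param time Numeric time points (same length).
#' @param n_bins Number of equal-count time bins (default 3).
#' @return A list: `wilcoxon_p` (first vs last bin), `spearman_rho`,
#'   `spearman_p`, `direction` (sign of rho).
#' @export
time_trend <- function(values, time, n_bins = 3) {
  stopifnot(length(values) == length(time), length(values) >= 4)
  bins <- cut(rank(time, ties.method = "first"), n_bins, labels = FALSE)
  w <- suppressWarnings(wilcoxon_rank_sum(values[bins == max(bins)],
                                          values[bins == 1]))
  ct <- suppressWarnings(stats::cor.test(values, time, method = "spearman"))
  list(wilcoxon_p = w$p_value,
       spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value,
       direction = sign(unname(ct$estimate)))
}

#' Assign MSI confidence levels from RT and drift agreement
#'
#' Level 1 requires an accepted MS2 match plus retention-time and
#' drift-time agreement with an authentic standard within the stated
#' tolerances; otherwise the match stays at level 2 (spectral match
#' only). A feature without an MS2 match is never upgraded.
#'
#' @param matches Tibble with `compound`, `rt`, `drift` (observed
#'   values per MS2-matched feature; `drift` may be NA).
#' @param standards Tibble with `compound`, `rt`, `drift` for the
#'   authentic standards.
#' @param rt_tol RT tolerance in minutes (default 0.1).
#' @param drift_tol Drift tolerance in 1/K0 units (default 0.02).
#' @return A tibble: `compound`, `msi_level` (1 or 2), `evidence`,
#'   `reason`.
#' @export
assign_confidence <- function(matches, standards, rt_tol = 0.1, drift_tol = 0.02) {
  i <- match(matches$compound, standards$compound)
  res <- lapply(seq_len(nrow(matches)), function(k) {
    if (is.na(i[k])) {
      return(tibble::tibble(compound = matches$compound[k], msi_level = 2L,
                            evidence = "ms2_only", reason = "no standard"))
    }
    drt <- abs(matches$rt[k] - standards$rt[i[k]])
    ddr <- abs(matches$drift[k] - standards$drift[i[k]])
    ok <- !is.na(drt) && !is.na(ddr) && drt <= rt_tol && ddr <= drift_tol
    tibble::tibble(
      compound = matches$compound[k],
      msi_level = if (ok) 1L else 2L,
      evidence = if (ok) "ms2+rt+drift" else "ms2_only",
      reason = if (ok) NA_character_
               else if (is.na(ddr)) "missing drift"
               else if (drt > rt_tol) "rt outside tolerance"
               else if (ddr > drift_tol) "drift outside tolerance"
               else NA_character_
    )
  })
  dplyr::bind_rows(res)
}
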