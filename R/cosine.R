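# Raw and modified cosine similarity between centroided MS2 spectra.
#
# Peak pairing is an exact maximum-total-score one-to-one assignment
# on the tolerance-feasible bipartite graph (solved per connected
# component by memoized bitmask recursion; per-spectrum-pair graphs
# are tiny). Ties in total score are broken by smaller summed |dm/z|,
# then by lower peak index, so results are deterministic.

.peak_weights <- function(sp, weighting) {
  w <- sp$peaks[, "intensity"]
  if (weighting == "sqrt") sqrt(w) else w
}

# feasible pairs (i from a, j from b); shifted matches compare
# mz_a against mz_b + shift
.candidate_pairs <- function(mza, mzb, frag_tol, shift = 0) {
  out <- list()
  if (length(mza) > 0 && length(mzb) > 0) {
    d <- outer(mza, mzb, function(x, y) abs(x - y))
    idx <- which(d <= frag_tol, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      out[[1]] <- data.frame(i = idx[, 1], j = idx[, 2],
                             dmz = d[idx], shifted = FALSE)
    }
    if (shift != 0) {
      ds <- outer(mza, mzb + shift, function(x, y) abs(x - y))
      idxs <- which(ds <= frag_tol, arr.ind = TRUE)
      if (nrow(idxs) > 0) {
        out[[2]] <- data.frame(i = idxs[, 1], j = idxs[, 2],
                               dmz = ds[idxs], shifted = TRUE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      dmz = numeric(0), shifted = logical(0)))
  }
  ed <- do.call(rbind, out)
  # a direct and a shifted variant of the same (i, j) cannot both be
  # used; keep the one with higher weight potential (same weight), so
  # smaller |dmz|
  ed <- ed[order(ed$i, ed$j, ed$dmz), , drop = FALSE]
  ed[!duplicated(ed[, c("i", "j")]), , drop = FALSE]
}

# exact max-weight matching on one connected component:
# edges: data.frame(i, j, w, dmz) with local indices; returns logical
# vector selecting edges
.component_matching <- function(edges, nA, nB) {
  if (nB > 24) stop("peak-matching component too dense (", nB, " peaks)")
  by_a <- split(seq_len(nrow(edges)), factor(edges$i, levels = seq_len(nA)))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  solve <- function(ai, mask) {
    if (ai > nA) return(c(0, 0))
    key <- paste0(ai, ".", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- solve(ai + 1, mask)             # leave peak ai unmatched
    for (k in by_a[[ai]]) {
      bit <- bitwShiftL(1L, edges$j[k] - 1L)
      if (bitwAnd(mask, bit) != 0) next
      sub <- solve(ai + 1, bitwOr(mask, bit))
      cand <- c(edges$w[k] + sub[1], edges$dmz[k] + sub[2])
      if (cand[1] > best[1] + 1e-12 ||
          (abs(cand[1] - best[1]) <= 1e-12 && cand[2] < best[2] - 1e-12)) {
        best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  opt <- solve(1L, 0L)
  # reconstruct deterministically: first feasible option (lower edge
  # index) achieving the optimum
  sel <- logical(nrow(edges))
  ai <- 1L; mask <- 0L; score <- opt[1]; dsum <- opt[2]
  while (ai <= nA) {
    skip <- solve(ai + 1, mask)
    taken <- FALSE
    for (k in by_a[[ai]]) {
      bit <- bitwShiftL(1L, edges$j[k] - 1L)
      if (bitwAnd(mask, bit) != 0) next
      sub <- solve(ai + 1, bitwOr(mask, bit))
      if (abs(edges$w[k] + sub[1] - score) <= 1e-9 &&
          abs(edges$dmz[k] + sub[2] - dsum) <= 1e-9 &&
          !(skip[1] > edges$w[k] + sub[1] + 1e-12)) {
        sel[k] <- TRUE
        mask <- bitwOr(mask, bit)
        score <- sub[1]; dsum <- sub[2]
        taken <- TRUE
        break
      }
    }
    if (!taken) { score <- skip[1]; dsum <- skip[2] }
    ai <- ai + 1L
  }
  sel
}

#' Pair peaks between two spectra
#'
#' Maximum-total-score one-to-one assignment of peaks of `a` to peaks
#' of `b`; peak i may pair with peak j directly
#' (|mz_a - mz_b| <= `frag_tol`) or, when `precursor_shift` is
#' non-zero, at the shifted position (|mz_a - (mz_b + shift)| <=
#' `frag_tol`). Scores are products of square-root (or raw)
#' intensities.
#'
#' @param a,b `spectrum` objects (centroided MS2).
#' @param frag_tol Fragment tolerance in Da.
#' @param precursor_shift Allowed precursor mass shift in Da (0 = raw).
#' @param weighting `"sqrt"` (default, GNPS convention) or `"none"`.
#' @return A data frame with columns `i`, `j`, `shifted`, `dmz`,
#'   `score` (one row per matched pair).
#' @export
match_peaks <- function(a, b, frag_tol = 0.02, precursor_shift = 0,
                        weighting = c("sqrt", "none")) {
  weighting <- match.arg(weighting)
  ed <- .candidate_pairs(a$peaks[, "mz"], b$peaks[, "mz"], frag_tol, precursor_shift)
  if (nrow(ed) == 0) {
    return(data.frame(i = integer(0), j = integer(0), shifted = logical(0),
                      dmz = numeric(0), score = numeric(0)))
  }
  wa <- .peak_weights(a, weighting); wb <- .peak_weights(b, weighting)
  ed$w <- wa[ed$i] * wb[ed$j]
  # connected components over the bipartite graph
  nA <- n_peaks(a); nB <- n_peaks(b)
  parent <- seq_len(nA + nB)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(ed))) {
    ra <- find(ed$i[k]); rb <- find(nA + ed$j[k])
    if (ra != rb) parent[rb] <- ra
  }
  comp_of_edge <- vapply(seq_len(nrow(ed)), function(k) find(ed$i[k]), integer(1))
  sel <- logical(nrow(ed))
  for (cc in unique(comp_of_edge)) {
    ke <- which(comp_of_edge == cc)
    sub <- ed[ke, , drop = FALSE]
    ia <- sort(unique(sub$i)); jb <- sort(unique(sub$j))
    loc <- data.frame(i = match(sub$i, ia), j = match(sub$j, jb),
                      w = sub$w, dmz = sub$dmz)
    sel[ke] <- .component_matching(loc, length(ia), length(jb))
  }
  out <- ed[sel, c("i", "j", "shifted", "dmz", "w")]
  names(out)[names(out) == "w"] <- "score"
  rownames(out) <- NULL
  out[order(out$i), , drop = FALSE]
}

.cosine_core <- function(a, b, frag_tol, shift, weighting) {
  wa <- .peak_weights(a, weighting); wb <- .peak_weights(b, weighting)
  na2 <- sum(wa^2); nb2 <- sum(wb^2)
  if ((n_peaks(a) > 0 && na2 == 0) || (n_peaks(b) > 0 && nb2 == 0)) {
    stop("degenerate spectrum: all intensities are zero")
  }
  if (n_peaks(a) == 0 || n_peaks(b) == 0) {
    return(list(cosine = 0, n_matched = 0L))
  }
  m <- match_peaks(a, b, frag_tol, shift, weighting)
  cosine <- sum(m$score) / sqrt(na2 * nb2)
  list(cosine = min(max(cosine, 0), 1), n_matched = nrow(m))
}

#' Raw cosine similarity
#'
#' Cosine of the two peak-intensity vectors under direct m/z matching
#' only. Symmetric; 1 for a non-empty spectrum against itself.
#'
#' @inheritParams match_peaks
#' @return A list with `cosine` in \[0, 1\] and `n_matched`.
#' @export
raw_cosine <- function(a, b, frag_tol = 0.02, weighting = c("sqrt", "none")) {
  .cosine_core(a, b, frag_tol, 0, match.arg(weighting))
}

#' Modified (precursor-shift-tolerant) cosine similarity
#'
#' As [raw_cosine()] but a peak may also match at an offset equal to
#' the precursor mass difference, the similarity used for molecular
#' networking. Never smaller than the raw cosine.
#'
#' @inheritParams match_peaks
#' @return A list with `cosine` in \[0, 1\] and `n_matched`.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02, weighting = c("sqrt", "none")) {
  if (is.na(a$precursor_mz) || is.na(b$precursor_mz)) {
    stop("modified cosine needs precursor m/z on both spectra")
  }
  .cosine_core(a, b, frag_tol, a$precursor_mz - b$precursor_mz, match.arg(weighting))
}
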