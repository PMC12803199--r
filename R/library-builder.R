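# Extraction and validation of reference MS2 spectra for enumerated
# targets from LC-MS/MS runs.
#
# An LC-MS run is a list with elements `file` (name), `ms1` and `ms2`
# (lists of `spectrum` objects). The feature finder is deliberately
# simple: a +/-ppm extracted-ion chromatogram with contiguous-segment
# peak picking and a fixed minimum width.

#' Extracted-ion chromatogram of one m/z
#'
#' @param run An LC-MS run (list with `ms1` spectra).
#' @param mz Target m/z.
#' @param ppm_tol Window half-width in ppm.
#' @return A tibble with `rt` (min) and `intensity` per MS1 scan.
#' @export
xic <- function(run, mz, ppm_tol = 10) {
  tol <- mz * ppm_tol / 1e6
  tibble::tibble(
    rt = vapply(run$ms1, function(s) s$rt, numeric(1)),
    intensity = vapply(run$ms1, function(s) {
      p <- s$peaks
      sum(p[abs(p[, "mz"] - mz) <= tol, "intensity"])
    }, numeric(1))
  )
}

# contiguous non-zero segments of an XIC; each is one feature
.xic_features <- function(tr, min_width = 0.2) {
  nz <- tr$intensity > 0
  if (!any(nz)) return(NULL)
  r <- rle(nz)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  segs <- which(r$values)
  out <- lapply(segs, function(s) {
    i <- starts[s]:ends[s]
    list(rt_lo = tr$rt[starts[s]], rt_hi = tr$rt[ends[s]],
         height = max(tr$intensity[i]))
  })
  out <- Filter(function(f) (f$rt_hi - f$rt_lo) >= min_width, out)
  if (length(out) == 0) NULL else out
}

#' Extract candidate library entries from one run
#'
#' For every (target, adduct) pair, an extracted-ion chromatogram at
#' the theoretical adduct m/z is searched for features, and every MS2
#' scan whose precursor lies within `ppm_tol` of the theoretical m/z
#' and whose retention time falls inside a feature window becomes one
#' candidate entry carrying the local MS1 intensity and the feature
#' height.
#'
#' @param run LC-MS run (list with `file`, `ms1`, `ms2`).
#' @param targets Target tibble from [enumerate_conjugates()].
#' @param adducts Adduct names to consider.
#' @param ppm_tol Precursor/XIC tolerance in ppm (default 10).
#' @param ms1_min Minimum MS1 intensity at the MS2 trigger
#'   (default 5e4).
#' @param height_min Minimum feature height (default 1e5).
#' @param min_width Minimum feature width in minutes (default 0.2).
#' @param apply_gates Filter on `ms1_min`/`height_min` here
#'   (default TRUE); [build_library()] defers them for auditing.
#' @return A tibble of unvalidated entries.
#' @export
extract_candidates <- function(run, targets, adducts = adduct_table()$name,
                               ppm_tol = 10, ms1_min = 5e4, height_min = 1e5,
                               min_width = 0.2, apply_gates = TRUE) {
  if (length(run$ms1) == 0 && length(run$ms2) == 0) {
    return(.empty_entries())
  }
  ms2_rt <- vapply(run$ms2, function(s) s$rt, numeric(1))
  ms2_prec <- vapply(run$ms2, function(s) s$precursor_mz, numeric(1))
  out <- list()
  for (t in seq_len(nrow(targets))) {
    for (ad in adducts) {
      theo <- adduct_mz(targets$mono_mass[t], ad)
      tol <- theo * ppm_tol / 1e6
      hit2 <- which(abs(ms2_prec - theo) <= tol)
      if (length(hit2) == 0) next
      tr <- xic(run, theo, ppm_tol)
      feats <- .xic_features(tr, min_width)
      if (is.null(feats)) next
      for (k in hit2) {
        feat <- Filter(function(f) ms2_rt[k] >= f$rt_lo && ms2_rt[k] <= f$rt_hi, feats)
        if (length(feat) == 0) next
        feat <- feat[[1]]
        near <- which.min(abs(tr$rt - ms2_rt[k]))
        out[[length(out) + 1]] <- tibble::tibble(
          target_id = targets$target_id[t], name = targets$name[t],
          head = targets$head[t], tail = targets$tail[t],
          adduct = ad, run_file = run$file, scan = k,
          provenance = paste0(run$file, ":", k),
          theoretical_mz = theo,
          observed_mz = ms2_prec[k],
          ms1_intensity = tr$intensity[near],
          feature_height = feat$height,
          spectrum = list(run$ms2[[k]])
        )
      }
    }
  }
  if (length(out) == 0) return(.empty_entries())
  res <- dplyr::bind_rows(out)
  if (apply_gates) {
    res <- res[res$ms1_intensity >= ms1_min & res$feature_height >= height_min, ,
               drop = FALSE]
  }
  res
}

.empty_entries <- function() {
  tibble::tibble(target_id = character(0), name = character(0),
                 head = character(0), tail = character(0),
                 adduct = character(0), run_file = character(0),
                 scan = integer(0), provenance = character(0),
                 theoretical_mz = numeric(0), observed_mz = numeric(0),
                 ms1_intensity = numeric(0), feature_height = numeric(0),
                 spectrum = list())
}

.subformula_cache <- new.env(parent = emptyenv())

# sorted vector of all protonated sub-formula masses of a parent
.subformula_masses <- function(parent_formula) {
  key <- format_formula(parent_formula)
  hit <- .subformula_cache[[key]]
  if (!is.null(hit)) return(hit)
  comp <- .canon_comp(parent_formula)
  grids <- lapply(comp, function(n) 0:n)
  g <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  # valence feasibility: a fragment needs at least one heavy atom and
  # cannot carry more hydrogens than 2C + N + 2 allows
  hc <- if ("H" %in% colnames(g)) g[, "H"] else 0
  cc <- if ("C" %in% colnames(g)) g[, "C"] else 0
  nc <- if ("N" %in% colnames(g)) g[, "N"] else 0
  heavy <- rowSums(g) - hc
  g <- g[heavy >= 1 & hc <= 2 * cc + nc + 2, , drop = FALSE]
  masses <- sort(as.numeric(g %*% .ELEMENT_MASSES[names(comp)]) + PROTON_MASS)
  .subformula_cache[[key]] <- masses
  masses
}

#' MS2 explanation score
#'
#' Fraction of total fragment intensity assignable to some protonated
#' sub-formula of the parent: a peak is explained when any composition
#' f with f <= parent (element-wise) satisfies
#' |mass(f) + 1.007276 - mz| <= `frag_tol`. Sub-formulas are
#' enumerated exhaustively over the element-count grid, restricted to
#' valence-feasible compositions (at least one heavy atom and
#' H <= 2C + N + 2); exhaustive enumeration is exact at the scale of
#' these conjugates (parents well below C60).
#'
#' @param spectrum An MS2 `spectrum`.
#' @param parent_formula Composition vector or formula string.
#' @param frag_tol Fragment tolerance in Da (default 0.01).
#' @return Explained-intensity fraction in \[0, 1\].
#' @export
ms2_explanation_score <- function(spectrum, parent_formula, frag_tol = 0.01) {
  if (is.character(parent_formula)) parent_formula <- parse_formula(parent_formula)
  stopifnot(length(parent_formula) > 0)
  pk <- spectrum$peaks
  if (nrow(pk) == 0) {
    warning("empty peak list; explanation score 0")
    return(0)
  }
  masses <- .subformula_masses(parent_formula)
  lo <- findInterval(pk[, "mz"] - frag_tol, masses, left.open = TRUE) + 1L
  hi <- findInterval(pk[, "mz"] + frag_tol, masses)
  explained <- hi >= lo
  tot <- sum(pk[, "intensity"])
  if (tot == 0) return(0)
  sum(pk[explained, "intensity"]) / tot
}

#' Diagnostic head-group fragment check
#'
#' TRUE when at least `min_diag` of the head's curated diagnostic
#' fragment m/z values are present in the spectrum within `frag_tol`.
#' The default policy requires all listed fragments. Heads with an
#' empty list pass vacuously and are flagged via the `"uncurated"`
#' attribute.
#'
#' @param spectrum An MS2 `spectrum`.
#' @param head One row of a head table, or a numeric vector of
#'   diagnostic m/z values.
#' @param frag_tol Tolerance in Da (default 0.01).
#' @param min_diag Minimum number of fragments required (default:
#'   all listed).
#' @return Logical scalar; attribute `uncurated` is TRUE when the
#'   head has no curated fragments.
#' @export
diagnostic_fragment_check <- function(spectrum, head, frag_tol = 0.01,
                                      min_diag = NULL) {
  frags <- if (is.numeric(head)) head else head$diagnostic_fragments[[1]]
  if (length(frags) == 0) {
    return(structure(TRUE, uncurated = TRUE))
  }
  if (is.null(min_diag)) min_diag <- length(frags)
  mz <- spectrum$peaks[, "mz"]
  present <- vapply(frags, function(f) any(abs(mz - f) <= frag_tol), logical(1))
  structure(sum(present) >= min_diag, uncurated = FALSE)
}

#' Adduct-inclusion rule
#'
#' Non-protonated adduct entries ([M+Na]+, [M+K]+, [M-H2O+H]+) of a
#' target are kept only if the same target also has an accepted
#' [M+H]+ or [M+NH4]+ entry; anchor adducts are never removed by this
#' rule.
#'
#' @param entries Entry tibble with columns `target_id`, `adduct` and
#'   logical `accepted`.
#' @return The tibble with `accepted` updated and a logical column
#'   `adduct_inclusion_pass`.
#' @export
apply_adduct_inclusion <- function(entries) {
  anchors <- c("[M+H]+", "[M+NH4]+")
  if (nrow(entries) == 0) {
    entries$adduct_inclusion_pass <- logical(0)
    return(entries)
  }
  anchored <- unique(entries$target_id[entries$accepted & entries$adduct %in% anchors])
  pass <- entries$adduct %in% anchors | entries$target_id %in% anchored
  entries$adduct_inclusion_pass <- pass
  entries$accepted <- entries$accepted & pass
  entries
}

#' Default gate configuration for [build_library()]
#' @return A named list of thresholds.
#' @export
library_gates <- function() {
  list(ppm_tol = 10, ms1_min = 5e4, height_min = 1e5, min_width = 0.2,
       frag_tol = 0.01, min_explanation = 0.6, min_diag = NULL)
}

#' Build a validated spectral library from reaction-mixture runs
#'
#' Pipeline composition of the extraction and validation gates:
#' precursor within ppm of the target adduct m/z, MS1 intensity and
#' feature-height floors, MS2 explanation score >= 0.6, head-group
#' diagnostic fragments present, and the adduct-inclusion rule. Each
#' rejected candidate is labeled with the first failing gate; failing
#' runs are reported and skipped, and an error is raised only if every
#' run fails.
#'
#' @param runs A list of LC-MS runs.
#' @param targets Target tibble from [enumerate_conjugates()].
#' @param heads Head table (source of diagnostic fragments).
#' @param adducts Adduct names to extract.
#' @param gates Gate configuration, see [library_gates()].
#' @return A list of class `spectral_library`: `entries` (all
#'   candidates with per-gate verdicts, an `accepted` flag and a
#'   `first_fail` label), `audit` (candidate counts per gate) and
#'   `gates`.
#' @export
build_library <- function(runs, targets, heads,
                          adducts = adduct_table()$name,
                          gates = library_gates()) {
  g <- utils::modifyList(library_gates(), gates)
  per_run <- list()
  failures <- character(0)
  for (r in seq_along(runs)) {
    res <- tryCatch(
      extract_candidates(runs[[r]], targets, adducts, ppm_tol = g$ppm_tol,
                         min_width = g$min_width, apply_gates = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d (%s): %s", r, runs[[r]]$file,
                                      conditionMessage(res)))
      next
    }
    per_run[[length(per_run) + 1]] <- res
  }
  if (length(per_run) == 0 && length(runs) > 0) {
    stop("all runs failed:\n  ", paste(failures, collapse = "\n  "))
  }
  if (length(failures) > 0) {
    warning("skipped failing runs:\n  ", paste(failures, collapse = "\n  "))
  }
  entries <- dplyr::bind_rows(per_run)
  if (nrow(entries) == 0) {
    entries <- .empty_entries()
    entries$explanation_score <- numeric(0)
    entries$diagnostic_pass <- logical(0)
    entries$uncurated <- logical(0)
    entries$accepted <- logical(0)
    entries$adduct_inclusion_pass <- logical(0)
    entries$first_fail <- character(0)
    return(structure(list(entries = entries, audit = .audit_table(entries),
                          gates = g, run_failures = failures),
                     class = "spectral_library"))
  }
  head_lookup <- stats::setNames(heads$diagnostic_fragments, heads$name)
  target_formula <- stats::setNames(targets$formula, targets$target_id)
  entries$explanation_score <- vapply(seq_len(nrow(entries)), function(i) {
    ms2_explanation_score(entries$spectrum[[i]],
                          target_formula[[entries$target_id[i]]], g$frag_tol)
  }, numeric(1))
  diag <- lapply(seq_len(nrow(entries)), function(i) {
    diagnostic_fragment_check(entries$spectrum[[i]],
                              head_lookup[[entries$head[i]]],
                              g$frag_tol, g$min_diag)
  })
  entries$diagnostic_pass <- vapply(diag, as.logical, logical(1))
  entries$uncurated <- vapply(diag, function(x) isTRUE(attr(x, "uncurated")), logical(1))
  gate_ms1 <- entries$ms1_intensity >= g$ms1_min
  gate_height <- entries$feature_height >= g$height_min
  gate_expl <- entries$explanation_score >= g$min_explanation
  entries$accepted <- gate_ms1 & gate_height & gate_expl & entries$diagnostic_pass
  entries <- apply_adduct_inclusion(entries)
  entries$first_fail <- dplyr::case_when(
    !gate_ms1 ~ "ms1_intensity",
    !gate_height ~ "feature_height",
    !gate_expl ~ "explanation_score",
    !entries$diagnostic_pass ~ "diagnostic_fragments",
    !entries$adduct_inclusion_pass ~ "adduct_inclusion",
    TRUE ~ NA_character_
  )
  structure(list(entries = entries, audit = .audit_table(entries),
                 gates = g, run_failures = failures),
            class = "spectral_library")
}

.audit_table <- function(entries) {
  gate_levels <- c("ms1_intensity", "feature_height", "explanation_score",
                   "diagnostic_fragments", "adduct_inclusion")
  tibble::tibble(
    gate = c("candidates", gate_levels, "accepted"),
    n = c(nrow(entries),
          unname(vapply(gate_levels,
                        function(gl) sum(entries$first_fail == gl, na.rm = TRUE),
                        numeric(1))),
          sum(entries$accepted))
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library: %d accepted / %d candidate spectra; %d unique compounds>\n",
              sum(x$entries$accepted), nrow(x$entries),
              length(unique(x$entries$name[x$entries$accepted]))))
  print(x$audit)
  invisible(x)
}

#' Accepted library entries as a search query table
#'
#' @param library A `spectral_library` from [build_library()], or an
#'   entries tibble.
#' @return A tibble with `query_id`, `name`, `head`, `tail`, `adduct`
#'   and the `spectrum` list-column, ready for [fasst_search()].
#' @export
library_query_table <- function(library) {
  entries <- if (inherits(library, "spectral_library")) library$entries else library
  acc <- entries[entries$accepted, , drop = FALSE]
  tibble::tibble(
    query_id = sprintf("%s|%s|%s", acc$target_id, acc$adduct, acc$provenance),
    name = acc$name, head = acc$head, tail = acc$tail, adduct = acc$adduct,
    spectrum = acc$spectrum
  )
}

#' Write an accepted library to MGF
#'
#' Spectrum blocks carry the compound name, adduct, SMILES and
#' explanation score, mirroring a shareable reference-library deposit.
#'
#' @param library A `spectral_library`.
#' @param targets Target tibble (source of SMILES).
#' @param path Output MGF path.
#' @return `path`, invisibly.
#' @export
write_library_mgf <- function(library, targets, path) {
  acc <- library$entries[library$entries$accepted, , drop = FALSE]
  smiles <- targets$smiles[match(acc$target_id, targets$target_id)]
  write_mgf(acc$spectrum, path, extra = tibble::tibble(
    name = acc$name, adduct = acc$adduct, smiles = smiles,
    explanation = sprintf("%.4f", acc$explanation_score),
    filename = acc$run_file
  ))
}

#' Read a library MGF back into a search query table
#'
#' Inverse of [write_library_mgf()]: spectrum blocks with NAME and
#' ADDUCT headers become query-table rows; head and tail are split
#' out of the compound name.
#'
#' @param path MGF path.
#' @return A tibble as from [library_query_table()].
#' @export
read_library_mgf <- function(path) {
  sps <- read_mgf(path)
  rows <- lapply(seq_along(sps), function(i) {
    f <- attr(sps[[i]], "fields")
    nm <- if ("NAME" %in% names(f)) f[["NAME"]] else sps[[i]]$provenance
    tail <- regmatches(nm, regexpr("3OH-C[0-9]+:[0-9]+", nm))
    tibble::tibble(
      query_id = paste0(sps[[i]]$provenance, "|", i),
      name = nm,
      head = trimws(sub(" ?3OH-C[0-9]+:[0-9]+.*$", "", nm)),
      tail = if (length(tail) == 1) tail else NA_character_,
      adduct = if ("ADDUCT" %in% names(f)) f[["ADDUCT"]] else NA_character_,
      spectrum = sps[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a GNPS-batch-style library table
#'
#' @param library A `spectral_library`.
#' @param targets Target tibble (for SMILES and exact mass).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, targets, path) {
  acc <- library$entries[library$entries$accepted, , drop = FALSE]
  i <- match(acc$target_id, targets$target_id)
  readr::write_tsv(tibble::tibble(
    filename = acc$run_file, compound_name = acc$name, adduct = acc$adduct,
    smiles = targets$smiles[i], exact_mass = targets$mono_mass[i],
    scan = acc$scan, explanation_score = acc$explanation_score
  ), path)
  invisible(path)
}
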