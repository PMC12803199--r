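# Centroided spectra and peak-list I/O.
#
# A spectrum is a light S3 record: an m/z-sorted two-column peak
# matrix plus acquisition fields. MGF is the interchange format; mzML
# files are read through mzR when available.

#' Construct a centroided spectrum
#'
#' @param mz,intensity Numeric vectors of equal length; `mz` must be
#'   strictly ascending (they are sorted and co-eluting duplicates
#'   rejected), intensities non-negative.
#' @param ms_level 1 or 2.
#' @param precursor_mz Precursor m/z (required > 0 for MS2).
#' @param rt Retention time in minutes.
#' @param drift Optional ion-mobility drift value (1/K0, V s/cm^2).
#' @param provenance USI-style identifier, conventionally `file:scan`.
#' @return An object of class `spectrum`.
#' @examples
#' sp <- new_spectrum(c(84.0444, 102.0550), c(100, 40), precursor_mz = 290.16)
#' @export
new_spectrum <- function(mz, intensity, ms_level = 2L, precursor_mz = NA_real_,
                         rt = NA_real_, drift = NA_real_, provenance = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative intensities")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(mz) > 1 && any(diff(mz) <= 0)) stop("peak m/z values must be strictly ascending")
  if (ms_level == 2 && (!is.na(precursor_mz)) && precursor_mz <= 0) {
    stop("MS2 spectra need a positive precursor m/z")
  }
  structure(list(
    ms_level = as.integer(ms_level), precursor_mz = precursor_mz,
    rt = rt, drift = drift,
    peaks = cbind(mz = mz, intensity = intensity),
    provenance = provenance
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum MS%d  %d peaks  precursor %.4f  rt %.2f min  %s>\n",
              x$ms_level, nrow(x$peaks),
              ifelse(is.na(x$precursor_mz), NA, x$precursor_mz),
              ifelse(is.na(x$rt), NA, x$rt),
              ifelse(is.na(x$provenance), "", x$provenance)))
  invisible(x)
}

n_peaks <- function(sp) nrow(sp$peaks)

#' Write spectra to an MGF file
#'
#' One `BEGIN IONS` block per spectrum. Standard fields (PEPMASS,
#' RTINSECONDS, SCANS, CHARGE) plus any extra annotation fields given
#' per spectrum are emitted as `KEY=value` headers. Peaks are written
#' to 5 decimals in m/z and 4 significant digits in intensity.
#'
#' @param spectra A list of `spectrum` objects.
#' @param path Output path.
#' @param extra Optional data frame / tibble of per-spectrum header
#'   fields (one row per spectrum; column names become keys).
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    lines <- c("BEGIN IONS",
               paste0("TITLE=", ifelse(is.na(sp$provenance), paste0("spectrum_", i), sp$provenance)))
    if (!is.na(sp$precursor_mz)) lines <- c(lines, sprintf("PEPMASS=%.5f", sp$precursor_mz))
    lines <- c(lines, "CHARGE=1+")
    if (!is.na(sp$rt)) lines <- c(lines, sprintf("RTINSECONDS=%.3f", sp$rt * 60))
    if (!is.na(sp$drift)) lines <- c(lines, sprintf("ION_MOBILITY=%.5f", sp$drift))
    lines <- c(lines, paste0("MSLEVEL=", sp$ms_level), paste0("SCANS=", i))
    if (!is.null(extra)) {
      for (key in names(extra)) {
        v <- extra[[key]][i]
        if (!is.na(v)) lines <- c(lines, paste0(toupper(key), "=", v))
      }
    }
    pk <- sp$peaks
    lines <- c(lines, sprintf("%.5f %.6g", pk[, "mz"], pk[, "intensity"]), "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an MGF file
#'
#' @param path MGF path.
#' @return A list of `spectrum` objects; header fields beyond the
#'   standard ones are attached as an attribute `fields` (named
#'   character vector) on each spectrum.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1):(ends[b] - 1)]
    is_hdr <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
    hdr <- block[is_hdr]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    names(vals) <- keys
    pk <- block[!is_hdr & nzchar(trimws(block))]
    mzint <- if (length(pk) > 0) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), function(x) as.numeric(x[1:2])))
      m
    } else matrix(numeric(0), ncol = 2)
    sp <- new_spectrum(
      mz = mzint[, 1], intensity = mzint[, 2],
      ms_level = if ("MSLEVEL" %in% keys) as.integer(vals[["MSLEVEL"]]) else 2L,
      precursor_mz = if ("PEPMASS" %in% keys) as.numeric(strsplit(vals[["PEPMASS"]], " ")[[1]][1]) else NA_real_,
      rt = if ("RTINSECONDS" %in% keys) as.numeric(vals[["RTINSECONDS"]]) / 60 else NA_real_,
      drift = if ("ION_MOBILITY" %in% keys) as.numeric(vals[["ION_MOBILITY"]]) else NA_real_,
      provenance = if ("TITLE" %in% keys) vals[["TITLE"]] else NA_character_
    )
    attr(sp, "fields") <- vals[setdiff(keys, c("PEPMASS", "CHARGE", "RTINSECONDS",
                                               "ION_MOBILITY", "MSLEVEL"))]
    out[[b]] <- sp
  }
  out
}

#' Read an mzML file into a list of spectra
#'
#' Thin wrapper over `mzR` for real instrument data. Profile-mode
#' spectra are rejected with a request to centroid first.
#'
#' @param path mzML path.
#' @return A list of `spectrum` objects (MS1 and MS2).
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package; convert to MGF otherwise")
  }
  h <- NULL
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  h <- mzR::header(fh)
  if (!is.null(h$centroided) && any(!h$centroided, na.rm = TRUE)) {
    stop("profile-mode spectra found; centroid the data (e.g. msconvert peakPicking) first")
  }
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  lapply(seq_len(nrow(h)), function(i) {
    p <- pks[[i]]
    new_spectrum(
      mz = p[, 1], intensity = p[, 2],
      ms_level = h$msLevel[i],
      precursor_mz = if (h$msLevel[i] > 1) h$precursorMZ[i] else NA_real_,
      rt = h$retentionTime[i] / 60,
      provenance = paste0(basename(path), ":", h$acquisitionNum[i])
    )
  })
}
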