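# Independent oracles, kept deliberately separate from the package's
# implementation paths: exhaustive assignment for cosine scores,
# permutation enumeration for the rank-sum test, and a recursive
# sub-formula enumerator for the explanation score.

# exhaustive maximum-score one-to-one peak assignment; returns the
# cosine (score / product of norms)
oracle_cosine <- function(a, b, frag_tol, shift = 0, weighting = "sqrt") {
  wa <- a$peaks[, "intensity"]; wb <- b$peaks[, "intensity"]
  if (weighting == "sqrt") { wa <- sqrt(wa); wb <- sqrt(wb) }
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  feas <- lapply(seq_along(mza), function(i) {
    which(abs(mza[i] - mzb) <= frag_tol |
            (shift != 0 & abs(mza[i] - (mzb + shift)) <= frag_tol))
  })
  best <- 0
  rec <- function(i, used, acc) {
    if (i > length(mza)) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(i + 1, used, acc)              # leave peak i unmatched
    for (j in feas[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1, used, acc + wa[i] * wb[j])
        used[j] <- FALSE
      }
    }
  }
  if (length(mza) > 0 && length(mzb) > 0) {
    rec(1, rep(FALSE, length(mzb)), 0)
  }
  denom <- sqrt(sum(wa^2) * sum(wb^2))
  if (denom == 0) return(0)
  min(best / denom, 1)
}

# exact two-sided rank-sum p-value by enumerating all group
# assignments (tie-free inputs)
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  centre <- m * n / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# recursive enumeration of protonated sub-formula masses of a parent
# (valence-feasible: >=1 heavy atom, H <= 2C + N + 2)
oracle_subformula_masses <- function(parent) {
  els <- names(parent)
  masses <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
              S = 31.97207117, P = 30.973762, Na = 22.98976928, K = 38.96370649)
  out <- numeric(0)
  counts <- integer(length(els))
  rec <- function(k) {
    if (k > length(els)) {
      cc <- if ("C" %in% els) counts[match("C", els)] else 0
      hh <- if ("H" %in% els) counts[match("H", els)] else 0
      nn <- if ("N" %in% els) counts[match("N", els)] else 0
      heavy <- sum(counts) - hh
      if (heavy >= 1 && hh <= 2 * cc + nn + 2) {
        out <<- c(out, sum(masses[els] * counts) + 1.007276)
      }
      return(invisible())
    }
    for (v in 0:parent[[k]]) {
      counts[k] <<- v
      rec(k + 1)
    }
    counts[k] <<- 0L
  }
  rec(1)
  sort(out)
}

oracle_explained_fraction <- function(spectrum, parent, frag_tol) {
  masses <- oracle_subformula_masses(parent)
  pk <- spectrum$peaks
  expl <- vapply(pk[, "mz"], function(m) any(abs(masses - m) <= frag_tol), logical(1))
  sum(pk[expl, "intensity"]) / sum(pk[, "intensity"])
}

# random centroided MS2 spectrum in a narrow m/z band (to provoke
# tolerance-window overlaps)
random_spectrum <- function(n_peaks, mz_lo = 100, mz_hi = 105, precursor = NULL) {
  mz <- sort(stats::runif(n_peaks, mz_lo, mz_hi))
  while (any(diff(mz) <= 1e-6)) mz <- sort(mz + cumsum(c(0, diff(mz) <= 1e-6)) * 1e-5)
  new_spectrum(mz, stats::runif(n_peaks, 1, 100),
               precursor_mz = if (is.null(precursor)) stats::runif(1, 200, 400) else precursor)
}
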