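# Positive-mode adduct arithmetic.

#' Supported positive-mode adducts
#'
#' Singly charged ion forms used throughout the library: protonated,
#' sodiated, potassiated, ammoniated, and the in-source water-loss
#' fragment of the protonated ion. Mass deltas fold the electron mass
#' into the charge carrier.
#'
#' @return A tibble with columns `name`, `mass_delta` (Da) and `charge`.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  tibble::tibble(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M-H2O+H]+"),
    mass_delta = c(1.007276, 22.989218, 38.963158, 18.033823, -17.003289),
    charge = 1L
  )
}

.adduct_delta <- function(adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (any(is.na(i))) {
    stop("unknown adduct(s): ", paste(adduct[is.na(i)], collapse = ", "),
         " (supported: ", paste(tab$name, collapse = ", "), ")")
  }
  tab$mass_delta[i]
}

#' m/z of an adducted ion
#'
#' @param M Neutral monoisotopic mass in Da (must be positive).
#' @param adduct Adduct name(s), e.g. `"[M+H]+"`; recycled against `M`.
#' @return Ion m/z (singly charged).
#' @examples
#' adduct_mz(161.068808, "[M+H]+")
#' @export
adduct_mz <- function(M, adduct) {
  stopifnot(all(M > 0))
  M + .adduct_delta(adduct)
}

#' Neutral mass back-calculated from an adducted m/z
#'
#' Inverse of [adduct_mz()].
#' @param mz Observed ion m/z.
#' @param adduct Adduct name(s).
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, adduct) {
  mz - .adduct_delta(adduct)
}
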