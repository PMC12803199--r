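# Elemental composition arithmetic and monoisotopic masses.
#
# A composition is a named integer vector (element -> count), e.g.
# c(C = 2, H = 5, N = 1, O = 2). Zero-count elements are dropped.

# CODATA/NIST monoisotopic atomic masses (Da), most abundant isotope,
# 8 decimal places.
.ELEMENT_MASSES <- c(
  C  = 12.00000000,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207117,
  P  = 30.97376200,
  Na = 22.98976928,
  K  = 38.96370649
)

#' Mass of the proton charge carrier (Da)
#'
#' Monoisotopic hydrogen minus the electron mass, the conventional mass
#' added by protonation in positive-mode ESI.
#' @export
PROTON_MASS <- 1.007276

#' Monoisotopic mass of water (Da)
#' @export
WATER_MASS <- 18.010565

.canon_comp <- function(comp) {
  comp <- comp[comp != 0]
  if (length(comp) == 0) return(stats::setNames(integer(0), character(0)))
  comp[order(names(comp))]
}

#' Parse a molecular formula string into a composition
#'
#' Accepts Hill-style formulas such as `"C6H11NO4"`. Only the elements
#' C, H, N, O, S, P, Na and K are supported.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C2H5NO2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (formula == "") return(.canon_comp(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed formula string: '", formula, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(el, names(.ELEMENT_MASSES))
  if (length(bad) > 0) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  comp <- tapply(n, el, sum)
  .canon_comp(stats::setNames(as.integer(comp), names(comp)))
}

#' Format a composition in Hill order
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically.
#'
#' @param comp Named integer composition vector.
#' @return A formula string.
#' @export
format_formula <- function(comp) {
  comp <- .canon_comp(comp)
  if (length(comp) == 0) return("")
  hill <- c(intersect(c("C", "H"), names(comp)),
            sort(setdiff(names(comp), c("C", "H"))))
  comp <- comp[hill]
  paste0(names(comp), ifelse(comp == 1, "", comp), collapse = "")
}

#' Add two compositions
#' @param a,b Named integer composition vectors.
#' @return The element-wise sum.
#' @export
comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .canon_comp(out)
}

#' Subtract one composition from another
#'
#' Errors if the result would contain a negative element count.
#' @param a,b Named integer composition vectors.
#' @return The element-wise difference `a - b`.
#' @export
comp_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    stop("composition subtraction went negative for: ",
         paste(names(out)[out < 0], collapse = ", "))
  }
  .canon_comp(out)
}

#' Monoisotopic mass of a composition or formula string
#'
#' @param formula Either a named integer composition vector or a single
#'   formula string (e.g. `"C2H5NO2"`).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")     # 18.010565
#' monoisotopic_mass(c(C = 2, H = 5, N = 1, O = 2))
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0) return(0)
  bad <- setdiff(names(formula), names(.ELEMENT_MASSES))
  if (length(bad) > 0) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(.ELEMENT_MASSES[names(formula)] * formula)
}
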