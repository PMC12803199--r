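# Amine head groups and 3-hydroxy fatty-acid tails.
#
# Heads are read from a TSV (name, smiles, diagnostic_fragments) and
# validated structurally: the SMILES must parse and contain at least
# one primary amine able to form an amide. Tails are named Cn:m
# ("3OH-C12:0" = 12 carbons, 0 unsaturations) and must carry one free
# carboxylic acid plus the C3 hydroxyl.

#' Parse a head-group table
#'
#' Reads a TSV with columns `name`, `smiles` and optionally
#' `diagnostic_fragments` (semicolon-separated m/z values). Each row is
#' parsed structurally; formula, monoisotopic mass and the number of
#' primary-amine conjugation sites are derived from the SMILES. Rows
#' with malformed SMILES or with no primary amine are reported as
#' errors naming the offending rows; input order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name`, `smiles`, `formula` (list of
#'   compositions), `formula_str`, `mono_mass`, `n_primary_amines`,
#'   `diagnostic_fragments` (list of numeric vectors).
#' @export
parse_head_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("name", "smiles") %in% names(raw))) {
    stop("head table must have columns 'name' and 'smiles'")
  }
  if (!"diagnostic_fragments" %in% names(raw)) raw$diagnostic_fragments <- NA_character_
  heads_from_rows(raw$name, raw$smiles, raw$diagnostic_fragments)
}

#' Build a head table from vectors
#'
#' Programmatic equivalent of [parse_head_table()].
#' @param name,smiles Character vectors.
#' @param diagnostic_fragments Optional character vector of
#'   semicolon-separated m/z lists.
#' @return See [parse_head_table()].
#' @export
heads_from_rows <- function(name, smiles, diagnostic_fragments = NULL) {
  if (is.null(diagnostic_fragments)) diagnostic_fragments <- rep(NA_character_, length(name))
  errs <- character(0)
  rows <- vector("list", length(name))
  for (i in seq_along(name)) {
    mol <- tryCatch(parse_smiles(smiles[i]), error = function(e) e)
    if (inherits(mol, "error")) {
      errs <- c(errs, sprintf("row %d (%s): %s", i, name[i], conditionMessage(mol)))
      next
    }
    sites <- find_primary_amines(mol)
    if (length(sites) == 0) {
      errs <- c(errs, sprintf(
        "row %d (%s): no primary amine available for conjugation", i, name[i]))
      next
    }
    comp <- mol_formula(mol)
    frag <- diagnostic_fragments[i]
    frags <- if (is.na(frag) || !nzchar(trimws(frag))) numeric(0)
             else as.numeric(strsplit(frag, ";", fixed = TRUE)[[1]])
    rows[[i]] <- tibble::tibble(
      name = name[i], smiles = smiles[i],
      formula = list(comp), formula_str = format_formula(comp),
      mono_mass = monoisotopic_mass(comp),
      n_primary_amines = length(sites),
      diagnostic_fragments = list(frags)
    )
  }
  if (length(errs) > 0) {
    stop("invalid head-group rows:\n  ", paste(errs, collapse = "\n  "))
  }
  dplyr::bind_rows(rows)
}

#' Parse a tail name of the form `3OH-Cn:m`
#'
#' @param name Character vector of tail names, e.g. `"3OH-C12:0"`.
#' @return A tibble with columns `carbons` and `unsaturations`.
#' @export
parse_tail_name <- function(name) {
  m <- regmatches(name, regexec("^3OH-C([0-9]+):([0-9]+)$", name))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("unparseable tail name(s): ", paste(name[bad], collapse = ", "))
  tibble::tibble(
    carbons = vapply(m, function(x) as.integer(x[2]), integer(1)),
    unsaturations = vapply(m, function(x) as.integer(x[3]), integer(1))
  )
}

#' Canonical tail name from chain description
#' @param carbons,unsaturations Integer vectors.
#' @return Character vector like `"3OH-C12:0"`.
#' @export
tail_name <- function(carbons, unsaturations) {
  sprintf("3OH-C%d:%d", carbons, unsaturations)
}

#' SMILES of a linear 3-hydroxy fatty acid
#'
#' Linear chain with a hydroxyl at C3 and a terminal carboxylic acid,
#' written omega-end first so the acid is the trailing `C(=O)O`.
#' Double bonds, when requested, are placed from carbon 5 upward at
#' every other position (delta-5, delta-7, ...).
#'
#' @param carbons Chain length (>= 4; >= 6 if unsaturated).
#' @param unsaturations Number of C=C double bonds (>= 0).
#' @return A SMILES string.
#' @examples
#' hydroxy_tail_smiles(12, 0)
#' @export
hydroxy_tail_smiles <- function(carbons, unsaturations = 0L) {
  stopifnot(carbons >= 3)
  if (carbons == 3) {
    if (unsaturations > 0) stop("C3 chain cannot hold a double bond here")
    return("OCCC(=O)O")  # 3-hydroxypropionic acid: the C3 hydroxyl is terminal
  }
  if (unsaturations > 0 && carbons < 5 + 2 * (unsaturations - 1) + 1) {
    stop("chain of ", carbons, " carbons cannot hold ", unsaturations, " double bond(s)")
  }
  doubles <- if (unsaturations > 0) 5 + 2 * (seq_len(unsaturations) - 1) else integer(0)
  # write atoms from carbon n down to carbon 1
  out <- "C"
  for (i in seq(carbons - 1, 1)) {
    bond <- if (i %in% doubles) "=" else ""  # bond between C(i+1) and C(i)
    tok <- if (i == 3) "C(O)" else if (i == 1) "C(=O)O" else "C"
    out <- paste0(out, bond, tok)
  }
  out
}

#' Parse a tail table
#'
#' Reads a TSV with columns `name` (Cn:m style) and `smiles`. The
#' SMILES is authoritative for structure; the name must be consistent
#' with the carbon and unsaturation counts recoverable from it.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name`, `carbons`, `unsaturations`,
#'   `smiles`, `formula` (list), `formula_str`, `mono_mass`.
#' @export
parse_tail_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("name", "smiles") %in% names(raw))) {
    stop("tail table must have columns 'name' and 'smiles'")
  }
  tails_from_rows(raw$name, raw$smiles)
}

#' Build a tail table from vectors
#'
#' Programmatic equivalent of [parse_tail_table()].
#' @param name,smiles Character vectors.
#' @return See [parse_tail_table()].
#' @export
tails_from_rows <- function(name, smiles) {
  cn <- parse_tail_name(name)
  rows <- vector("list", length(name))
  errs <- character(0)
  for (i in seq_along(name)) {
    mol <- tryCatch(parse_smiles(smiles[i]), error = function(e) e)
    if (inherits(mol, "error")) {
      errs <- c(errs, sprintf("row %d (%s): %s", i, name[i], conditionMessage(mol)))
      next
    }
    comp <- mol_formula(mol)
    # expected CnH(2n-2u)O3 for a hydroxy acid with u double bonds
    want <- c(C = cn$carbons[i], H = 2L * cn$carbons[i] - 2L * cn$unsaturations[i], O = 3L)
    if (!identical(.canon_comp(comp), .canon_comp(want))) {
      errs <- c(errs, sprintf(
        "row %d (%s): SMILES formula %s inconsistent with name (expected %s)",
        i, name[i], format_formula(comp), format_formula(want)))
      next
    }
    if (is.na(.find_carboxyl(mol))) {
      errs <- c(errs, sprintf("row %d (%s): no free carboxylic acid", i, name[i]))
      next
    }
    rows[[i]] <- tibble::tibble(
      name = name[i], carbons = cn$carbons[i], unsaturations = cn$unsaturations[i],
      smiles = smiles[i], formula = list(comp),
      formula_str = format_formula(comp), mono_mass = monoisotopic_mass(comp)
    )
  }
  if (length(errs) > 0) stop("invalid tail rows:\n  ", paste(errs, collapse = "\n  "))
  dplyr::bind_rows(rows)
}

# carboxyl carbon: C with one =O and one -OH (O with no other heavy
# neighbour); returns the carbon index or NA
.find_carboxyl <- function(mol) {
  h <- mol_h_counts(mol)
  for (i in which(mol$atoms$element == "C" & !mol$atoms$aromatic)) {
    nb <- .neighbors(mol, i)
    os <- nb[mol$atoms$element[nb] == "O"]
    if (length(os) < 2) next
    dbl <- any(vapply(os, function(k) mol$bonds$order[.bond_between(mol, i, k)] == 2, logical(1)))
    oh <- os[vapply(os, function(k) {
      mol$bonds$order[.bond_between(mol, i, k)] == 1 && h[k] == 1 &&
        length(.neighbors(mol, k)) == 1
    }, logical(1))]
    if (dbl && length(oh) >= 1) return(i)
  }
  NA_integer_
}
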