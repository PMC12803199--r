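# Combinatorial head x tail amide conjugates.
#
# Condensation of a primary amine with the tail's carboxylic acid:
# the conjugate formula is head + tail - H2O, and a head with k
# primary amines yields k positional isomers per tail.

# parsed molecular graphs are immutable; memoize by SMILES string so
# enumeration does not re-parse each head for every tail
.mol_cache <- new.env(parent = emptyenv())
.parse_smiles_cached <- function(smiles) {
  hit <- .mol_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  mol <- parse_smiles(smiles)
  .mol_cache[[smiles]] <- mol
  mol
}

#' Assemble one amide conjugate
#'
#' Forms the amide bond between the `site_index`-th primary amine of
#' the head and the tail's free carboxylic acid at the graph level:
#' the acid hydroxyl is removed, the amine nitrogen is bonded to the
#' carbonyl carbon, and a fresh SMILES is written from the merged
#' graph. The result is validated against the elemental bookkeeping
#' head + tail - H2O.
#'
#' @param head One row of a head table (see [parse_head_table()]).
#' @param tail One row of a tail table (see [parse_tail_table()]).
#' @param site_index Which primary amine to acylate (1-based).
#' @return A one-row tibble with columns `name`, `head`, `tail`,
#'   `isomer_index`, `smiles`, `formula` (list), `formula_str`,
#'   `mono_mass`.
#' @export
assemble_amide <- function(head, tail, site_index = 1L) {
  mol_h <- .parse_smiles_cached(head$smiles)
  mol_t <- .parse_smiles_cached(tail$smiles)
  sites <- find_primary_amines(mol_h)
  if (site_index < 1 || site_index > length(sites)) {
    stop("site_index ", site_index, " out of range: head '", head$name,
         "' has ", length(sites), " primary amine(s)")
  }
  cx <- .find_carboxyl(mol_t)
  if (is.na(cx)) stop("tail '", tail$name, "' has no free carboxylic acid")
  hmt <- mol_h_counts(mol_t)
  oh <- {
    nb <- .neighbors(mol_t, cx)
    os <- nb[mol_t$atoms$element[nb] == "O"]
    os[vapply(os, function(k) {
      mol_t$bonds$order[.bond_between(mol_t, cx, k)] == 1 && hmt[k] == 1
    }, logical(1))][1]
  }
  # merge graphs: tail atoms first (minus the acid OH oxygen), then head
  keep_t <- setdiff(seq_len(nrow(mol_t$atoms)), oh)
  remap_t <- stats::setNames(seq_along(keep_t), keep_t)
  bonds_t <- mol_t$bonds[mol_t$bonds$a != oh & mol_t$bonds$b != oh, , drop = FALSE]
  bonds_t$a <- remap_t[as.character(bonds_t$a)]
  bonds_t$b <- remap_t[as.character(bonds_t$b)]
  off <- length(keep_t)
  bonds_h <- mol_h$bonds
  bonds_h$a <- bonds_h$a + off
  bonds_h$b <- bonds_h$b + off
  atoms <- rbind(mol_t$atoms[keep_t, , drop = FALSE], mol_h$atoms)
  rownames(atoms) <- NULL
  n_idx <- sites[site_index] + off
  # the conjugated N loses one implicit H; drop any explicit-H bracket
  atoms$bracket[n_idx] <- FALSE
  atoms$h_explicit[n_idx] <- NA_integer_
  amide <- data.frame(a = remap_t[as.character(cx)], b = n_idx, order = 1)
  mol <- structure(list(atoms = atoms,
                        bonds = rbind(bonds_t, bonds_h, amide)),
                   class = "mol")
  smiles <- write_smiles(mol, root = 1L)
  comp <- comp_subtract(comp_add(head$formula[[1]], tail$formula[[1]]),
                        c(H = 2L, O = 1L))
  got <- mol_formula(parse_smiles(smiles))
  if (!identical(.canon_comp(got), .canon_comp(comp))) {
    stop("internal error: assembled SMILES formula ", format_formula(got),
         " != head + tail - H2O (", format_formula(comp), ")")
  }
  tibble::tibble(
    name = paste0(head$name, " ", tail$name),
    head = head$name, tail = tail$name,
    isomer_index = as.integer(site_index),
    smiles = smiles, formula = list(comp),
    formula_str = format_formula(comp),
    mono_mass = monoisotopic_mass(comp)
  )
}

#' Enumerate all head x tail conjugate targets
#'
#' Every (head, tail) pair is expanded into one target per primary
#' amine of the head, in deterministic order: head-table order, then
#' tail-table order, then isomer index.
#'
#' @param heads Head table from [parse_head_table()].
#' @param tails Tail table from [parse_tail_table()].
#' @param adducts Adduct names for which m/z columns are added
#'   (default: all of [adduct_table()]).
#' @return A tibble of conjugate targets with one `mz_<adduct>` column
#'   per requested adduct and a unique `target_id`.
#' @examples
#' \donttest{
#' st <- generate_heads_tails(n_heads = 2, n_tails = 3, seed = 1)
#' enumerate_conjugates(st$heads, st$tails)
#' }
#' @export
enumerate_conjugates <- function(heads, tails, adducts = adduct_table()$name) {
  stopifnot(nrow(heads) > 0, nrow(tails) > 0)
  dup_h <- unique(heads$name[duplicated(heads$name)])
  dup_t <- unique(tails$name[duplicated(tails$name)])
  if (length(dup_h) + length(dup_t) > 0) {
    stop("duplicate names in input tables: ",
         paste(c(dup_h, dup_t), collapse = ", "))
  }
  out <- vector("list", nrow(heads) * nrow(tails))
  k <- 0
  for (i in seq_len(nrow(heads))) {
    for (j in seq_len(nrow(tails))) {
      n_iso <- heads$n_primary_amines[i]
      iso <- lapply(seq_len(n_iso), function(s) {
        row <- assemble_amide(heads[i, ], tails[j, ], s)
        if (n_iso > 1) row$name <- paste0(row$name, " (isomer ", s, ")")
        row
      })
      k <- k + 1
      out[[k]] <- dplyr::bind_rows(iso)
    }
  }
  res <- dplyr::bind_rows(out)
  res$target_id <- sprintf("T%04d", seq_len(nrow(res)))
  for (ad in adducts) {
    res[[paste0("mz_", ad)]] <- adduct_mz(res$mono_mass, ad)
  }
  res
}

#' Write an enumerated target list to TSV
#'
#' Flat text export (list-columns dropped) with the formula in Hill
#' order and one m/z column per adduct.
#' @param targets Tibble from [enumerate_conjugates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_tsv <- function(targets, path) {
  flat <- targets[, setdiff(names(targets), "formula")]
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Read a target list written by [write_targets_tsv()]
#' @param path TSV path.
#' @return A tibble with the `formula` list-column restored.
#' @export
read_targets_tsv <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols())
  flat$formula <- lapply(flat$formula_str, parse_formula)
  flat
}
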