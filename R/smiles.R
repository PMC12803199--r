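# Minimal SMILES support for amine head groups and hydroxy fatty-acid
# tails: organic-subset atoms (B C N O P S F Cl Br I, aromatic b c n o
# s p), bracket atoms with explicit H and charge, branches, ring
# closures, and bond orders - = # :. Implicit hydrogens follow the
# standard valence model (aromatic bonds count 1.5, rounded up).
# Stereo markers (/ \ @) are accepted and ignored; disconnected
# (dotted) SMILES are rejected.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SUBSET <- c("b", "c", "n", "o", "s", "p")
.VALENCES <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
                  F = 1, Cl = 1, Br = 1, I = 1)

.implicit_h <- function(element, bondsum) {
  vals <- .VALENCES[[element]]
  if (is.null(vals)) return(0L)
  deg <- ceiling(bondsum - 1e-6)
  ok <- vals[vals >= deg]
  if (length(ok) == 0) return(0L)
  as.integer(min(ok) - deg)
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A single SMILES string (one connected molecule).
#' @return An object of class `mol`: a list with `atoms`
#'   (element, aromatic, charge, bracket, h_explicit) and `bonds`
#'   (a, b, order; aromatic bonds have order 1.5).
#' @examples
#' parse_smiles("NCC(=O)O")   # glycine
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || nchar(smiles) == 0) stop("empty SMILES")
  ch <- strsplit(smiles, "")[[1]]
  n <- length(ch)
  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  bracket <- logical(0); h_explicit <- integer(0)
  bond_a <- integer(0); bond_b <- integer(0); bond_o <- numeric(0)
  prev <- NA_integer_; stack <- integer(0); pending <- NA_real_
  ring <- list()  # digit label -> list(atom, order)

  add_bond <- function(a, b, order) {
    if (is.na(order)) order <- if (aromatic[a] && aromatic[b]) 1.5 else 1
    bond_a <<- c(bond_a, a); bond_b <<- c(bond_b, b); bond_o <<- c(bond_o, order)
  }
  add_atom <- function(el, arom, chg, brk, hexp) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg); bracket <<- c(bracket, brk)
    h_explicit <<- c(h_explicit, hexp)
    idx <- length(element)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    prev <<- idx; pending <<- NA_real_
    idx
  }
  close_ring <- function(lab) {
    if (is.na(prev)) stop("ring-closure digit before any atom in '", smiles, "'")
    if (!is.null(ring[[lab]])) {
      open <- ring[[lab]]
      order <- if (!is.na(pending)) pending else open$order
      add_bond(open$atom, prev, order)
      ring[[lab]] <<- NULL
    } else {
      ring[[lab]] <- list(atom = prev, order = pending)
      ring <<- ring
    }
    pending <<- NA_real_
  }

  i <- 1
  while (i <= n) {
    c1 <- ch[i]
    if (c1 %in% c("-", "/", "\\")) { pending <- 1; i <- i + 1 }
    else if (c1 == "=") { pending <- 2; i <- i + 1 }
    else if (c1 == "#") { pending <- 3; i <- i + 1 }
    else if (c1 == ":") { pending <- 1.5; i <- i + 1 }
    else if (c1 == "(") {
      if (is.na(prev)) stop("branch before any atom in '", smiles, "'")
      stack <- c(stack, prev); i <- i + 1
    }
    else if (c1 == ")") {
      if (length(stack) == 0) stop("unbalanced ')' in '", smiles, "'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    }
    else if (grepl("[0-9]", c1)) { close_ring(c1); i <- i + 1 }
    else if (c1 == "%") {
      if (i + 2 > n) stop("truncated %% ring label in '", smiles, "'")
      close_ring(paste0(ch[i + 1], ch[i + 2])); i <- i + 3
    }
    else if (c1 == ".") stop("disconnected (dotted) SMILES not supported: '", smiles, "'")
    else if (c1 == "[") {
      j <- i + 1
      while (j <= n && ch[j] != "]") j <- j + 1
      if (j > n) stop("unterminated bracket atom in '", smiles, "'")
      body <- paste0(ch[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z])(@{0,2})(H[0-9]*)?([+-][0-9]*|\\++|-+)?$", body))[[1]]
      if (length(m) == 0) stop("malformed bracket atom [", body, "] in '", smiles, "'")
      sym <- m[3]
      arom <- sym %in% .AROMATIC_SUBSET || sym == tolower(sym)
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      if (!el %in% names(.ELEMENT_MASSES)) stop("unsupported element [", sym, "] in '", smiles, "'")
      hx <- m[5]
      hexp <- if (is.na(hx) || hx == "") 0L
              else if (hx == "H") 1L else as.integer(substring(hx, 2))
      cg <- m[6]
      chg <- if (is.na(cg) || cg == "") 0L
             else if (grepl("^\\++$", cg)) nchar(cg)
             else if (grepl("^-+$", cg)) -nchar(cg)
             else as.integer(paste0(substr(cg, 1, 1), "1")) *
                  max(1L, suppressWarnings(as.integer(substring(cg, 2))), na.rm = TRUE)
      add_atom(el, arom, as.integer(chg), TRUE, hexp)
      i <- j + 1
    }
    else {
      two <- if (i < n) paste0(c1, ch[i + 1]) else ""
      if (two %in% c("Cl", "Br")) { add_atom(two, FALSE, 0L, FALSE, NA_integer_); i <- i + 2 }
      else if (c1 %in% .ORGANIC_SUBSET) { add_atom(c1, FALSE, 0L, FALSE, NA_integer_); i <- i + 1 }
      else if (c1 %in% .AROMATIC_SUBSET) {
        add_atom(toupper(c1), TRUE, 0L, FALSE, NA_integer_); i <- i + 1
      }
      else stop("unexpected character '", c1, "' at position ", i, " in '", smiles, "'")
    }
  }
  if (length(stack) > 0) stop("unbalanced '(' in '", smiles, "'")
  if (length(ring) > 0) stop("unclosed ring bond(s) in '", smiles, "'")
  if (length(element) == 0) stop("no atoms in '", smiles, "'")
  structure(list(
    atoms = data.frame(element = element, aromatic = aromatic, charge = charge,
                       bracket = bracket, h_explicit = h_explicit,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a = bond_a, b = bond_b, order = bond_o)
  ), class = "mol")
}

.bondsum <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a[k]] <- s[mol$bonds$a[k]] + mol$bonds$order[k]
      s[mol$bonds$b[k]] <- s[mol$bonds$b[k]] + mol$bonds$order[k]
    }
  }
  s
}

#' Per-atom hydrogen counts of a molecular graph
#'
#' Explicit bracket hydrogens where stated, otherwise the implicit
#' count from the standard valence model.
#' @param mol A `mol` object from [parse_smiles()].
#' @return Integer vector, one entry per heavy atom.
#' @export
mol_h_counts <- function(mol) {
  bs <- .bondsum(mol)
  vapply(seq_len(nrow(mol$atoms)), function(i) {
    if (mol$atoms$bracket[i]) mol$atoms$h_explicit[i]
    else .implicit_h(mol$atoms$element[i], bs[i])
  }, integer(1))
}

#' Elemental composition of a molecular graph
#'
#' @param mol A `mol` object (or a SMILES string, parsed on the fly).
#' @return Named integer composition vector including hydrogens.
#' @examples
#' format_formula(mol_formula("NCC(=O)O"))  # "C2H5NO2"
#' @export
mol_formula <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  comp <- table(mol$atoms$element)
  comp <- stats::setNames(as.integer(comp), names(comp))
  h <- sum(mol_h_counts(mol))
  if (h > 0) comp <- comp_add(comp, c(H = as.integer(h)))
  .canon_comp(comp)
}

.neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$b[b$a == i], b$a[b$b == i])
}

.bond_between <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a == i & b$b == j) | (b$a == j & b$b == i))
  if (length(k) == 0) NA_integer_ else k[1]
}

#' Find primary-amine conjugation sites
#'
#' A primary amine here is a non-aromatic, uncharged nitrogen carrying
#' exactly two hydrogens and bonded to a single carbon, excluding amide
#' nitrogens (the carbon bears a C=O) and guanidino nitrogens (the
#' carbon bears a C=N and at least two nitrogens). Aromatic ring NH
#' (e.g. the imidazole of histamine) is never a site.
#'
#' @param mol A `mol` object or SMILES string.
#' @return Integer atom indices in order of appearance (possibly empty).
#' @examples
#' length(find_primary_amines("NCCCC(N)C(=O)O"))  # ornithine: 2
#' @export
find_primary_amines <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  h <- mol_h_counts(mol)
  sites <- integer(0)
  for (i in seq_len(nrow(mol$atoms))) {
    at <- mol$atoms[i, ]
    if (at$element != "N" || at$aromatic || at$charge != 0 || h[i] != 2) next
    nb <- .neighbors(mol, i)
    if (length(nb) != 1) next
    j <- nb[1]
    if (mol$atoms$element[j] != "C") next
    # exclude amide N: attached carbon double-bonded to O
    jn <- .neighbors(mol, j)
    is_amide <- any(vapply(jn, function(k) {
      mol$atoms$element[k] == "O" &&
        mol$bonds$order[.bond_between(mol, j, k)] == 2
    }, logical(1)))
    if (is_amide) next
    # exclude guanidino N: attached carbon with C=N and >=2 N neighbours
    n_nbrs <- sum(mol$atoms$element[jn] == "N")
    has_cn_double <- any(vapply(jn, function(k) {
      mol$atoms$element[k] == "N" &&
        mol$bonds$order[.bond_between(mol, j, k)] == 2
    }, logical(1)))
    if (has_cn_double && n_nbrs >= 2) next
    sites <- c(sites, i)
  }
  sites
}

#' Write a molecular graph back to SMILES
#'
#' Depth-first traversal from `root` with ring-closure digits for cycle
#' bonds. The output re-parses to an identical elemental composition.
#'
#' @param mol A `mol` object.
#' @param root Atom index to start from (default 1).
#' @return A SMILES string.
#' @export
write_smiles <- function(mol, root = 1L) {
  natoms <- nrow(mol$atoms)
  stopifnot(root >= 1, root <= natoms)
  h <- mol_h_counts(mol)
  bs <- .bondsum(mol)
  adj <- vector("list", natoms)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
  }
  other <- function(k, i) if (mol$bonds$a[k] == i) mol$bonds$b[k] else mol$bonds$a[k]

  visited <- logical(natoms); used <- logical(max(1, nrow(mol$bonds)))
  children <- vector("list", natoms)   # tree edges, bond ids in DFS order
  backs <- vector("list", natoms)      # ring digits per atom: list(digit, order, first)
  digit_next <- 0L
  # iterative DFS to collect tree and back edges
  stack_ <- list(root); visited[root] <- TRUE
  order_seen <- integer(0)
  dfs <- function(i) {
    visited[i] <<- TRUE
    for (k in adj[[i]]) {
      if (used[k]) next
      j <- other(k, i)
      if (!visited[j]) {
        used[k] <<- TRUE
        children[[i]] <<- c(children[[i]], k)
        dfs(j)
      } else {
        used[k] <<- TRUE
        digit_next <<- digit_next + 1L
        if (digit_next > 9L) stop("more than 9 ring closures not supported")
        backs[[j]] <<- c(backs[[j]], list(list(digit = digit_next, order = mol$bonds$order[k], first = TRUE)))
        backs[[i]] <<- c(backs[[i]], list(list(digit = digit_next, order = mol$bonds$order[k], first = FALSE)))
      }
    }
  }
  dfs(root)
  if (!all(visited)) stop("molecular graph is disconnected")

  bondsym <- function(order, i, j) {
    if (order == 2) "="
    else if (order == 3) "#"
    else if (order == 1 && mol$atoms$aromatic[i] && mol$atoms$aromatic[j]) "-"
    else ""
  }
  token <- function(i) {
    at <- mol$atoms[i, ]
    sym <- if (at$aromatic) tolower(at$element) else at$element
    plain_ok <- at$charge == 0 &&
      ((at$aromatic && tolower(at$element) %in% .AROMATIC_SUBSET) ||
       (!at$aromatic && at$element %in% .ORGANIC_SUBSET)) &&
      .implicit_h(at$element, bs[i]) == h[i]
    if (plain_ok) return(sym)
    hs <- if (h[i] == 0) "" else if (h[i] == 1) "H" else paste0("H", h[i])
    cg <- if (at$charge == 0) "" else if (at$charge > 0) {
      if (at$charge == 1) "+" else paste0("+", at$charge)
    } else {
      if (at$charge == -1) "-" else paste0("-", abs(at$charge))
    }
    paste0("[", sym, hs, cg, "]")
  }
  emit <- function(i) {
    out <- token(i)
    for (bk in backs[[i]]) {
      pre <- if (bk$order == 2) "=" else if (bk$order == 3) "#" else ""
      out <- paste0(out, if (bk$first) pre else "", bk$digit)
    }
    ks <- children[[i]]
    if (length(ks) > 0) {
      for (idx in seq_along(ks)) {
        k <- ks[idx]; j <- other(k, i)
        part <- paste0(bondsym(mol$bonds$order[k], i, j), emit(j))
        out <- paste0(out, if (idx < length(ks)) paste0("(", part, ")") else part)
      }
    }
    out
  }
  emit(root)
}
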