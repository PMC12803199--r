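# Repository-style batch search and molecular networking.

#' Build a corpus table from per-file spectrum lists
#'
#' @param files A named list: file name -> list of `spectrum` objects
#'   (MS2). Scan numbers are positions within each file.
#' @return A tibble with columns `corpus_file`, `scan`, `precursor_mz`
#'   and a `spectrum` list-column, the input format of
#'   [fasst_search()].
#' @export
corpus_table <- function(files) {
  stopifnot(is.list(files), !is.null(names(files)))
  rows <- lapply(names(files), function(fn) {
    sps <- files[[fn]]
    tibble::tibble(
      corpus_file = fn,
      scan = seq_along(sps),
      precursor_mz = vapply(sps, function(s) s$precursor_mz, numeric(1)),
      spectrum = sps
    )
  })
  dplyr::bind_rows(rows)
}

#' Search a spectral library against a corpus
#'
#' MASST/FASST-style batch search: every library spectrum is compared
#' (raw cosine) against all corpus spectra whose precursor m/z lies
#' within `prec_tol`; matches are reported when the cosine and
#' matched-ion gates pass. A sorted precursor index prunes candidates
#' without changing the result set.
#'
#' @param library A tibble with columns `query_id` and `spectrum`
#'   (list of `spectrum`), e.g. from [library_query_table()].
#' @param corpus A tibble from [corpus_table()].
#' @param prec_tol Precursor tolerance in Da (default 0.02).
#' @param frag_tol Fragment tolerance in Da (default 0.02).
#' @param min_cos Minimum raw cosine (default 0.7).
#' @param min_matched Minimum number of matched ions (default 3).
#' @param weighting Intensity weighting for the cosine.
#' @param index Use the precursor index (`FALSE` forces the all-pairs
#'   scan; results are identical).
#' @return A tibble: `query_id`, `corpus_file`, `scan`, `cosine`,
#'   `n_matched`, `precursor_delta`.
#' @export
fasst_search <- function(library, corpus, prec_tol = 0.02, frag_tol = 0.02,
                         min_cos = 0.7, min_matched = 3L,
                         weighting = c("sqrt", "none"), index = TRUE) {
  weighting <- match.arg(weighting)
  if (nrow(corpus) == 0 || nrow(library) == 0) {
    return(tibble::tibble(query_id = character(0), corpus_file = character(0),
                          scan = integer(0), cosine = numeric(0),
                          n_matched = integer(0), precursor_delta = numeric(0)))
  }
  ord <- order(corpus$precursor_mz)
  prec_sorted <- corpus$precursor_mz[ord]
  out <- list()
  for (q in seq_len(nrow(library))) {
    qs <- library$spectrum[[q]]
    qmz <- qs$precursor_mz
    cand <- if (index) {
      lo <- findInterval(qmz - prec_tol, prec_sorted, left.open = TRUE) + 1L
      hi <- findInterval(qmz + prec_tol, prec_sorted)
      if (hi < lo) integer(0) else ord[lo:hi]
    } else {
      which(abs(corpus$precursor_mz - qmz) <= prec_tol)
    }
    for (ci in cand) {
      delta <- qmz - corpus$precursor_mz[ci]
      if (abs(delta) > prec_tol) next
      cs <- raw_cosine(qs, corpus$spectrum[[ci]], frag_tol, weighting)
      if (cs$cosine >= min_cos && cs$n_matched >= min_matched) {
        out[[length(out) + 1]] <- tibble::tibble(
          query_id = library$query_id[q],
          corpus_file = corpus$corpus_file[ci],
          scan = corpus$scan[ci],
          cosine = cs$cosine, n_matched = as.integer(cs$n_matched),
          precursor_delta = delta
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(query_id = character(0), corpus_file = character(0),
                          scan = integer(0), cosine = numeric(0),
                          n_matched = integer(0), precursor_delta = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Write / read a match table (MASST-style TSV)
#' @param matches Tibble from [fasst_search()].
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_matches_tsv <- function(matches, path) {
  readr::write_tsv(matches, path)
  invisible(path)
}

#' @rdname write_matches_tsv
#' @export
read_matches_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols())
}

#' Build a molecular network from feature spectra
#'
#' Edges connect feature pairs whose modified cosine and matched-ion
#' count pass the gates. Undirected, canonically ordered
#' (`feature_a` before `feature_b` in input order), no self-edges.
#'
#' @param features A tibble with columns `feature_id` and `spectrum`
#'   (list of MS2 `spectrum` objects with precursor m/z).
#' @param min_cos Minimum modified cosine (default 0.7).
#' @param min_matched Minimum matched peaks (default 2; reference
#'   spectra of short-chain conjugates and alkali adducts can have
#'   very few fragments).
#' @param frag_tol Fragment tolerance in Da.
#' @param top_k Optional per-node edge cap: keep an edge only if it
#'   ranks within the top `top_k` by cosine for both endpoints
#'   (default `NULL` = off).
#' @return A tibble: `feature_a`, `feature_b`, `cosine`, `delta_mass`
#'   (precursor_a - precursor_b), `n_matched`.
#' @export
build_network <- function(features, min_cos = 0.7, min_matched = 2L,
                          frag_tol = 0.02, top_k = NULL) {
  n <- nrow(features)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        a <- features$spectrum[[i]]; b <- features$spectrum[[j]]
        cs <- modified_cosine(a, b, frag_tol)
        if (cs$cosine >= min_cos && cs$n_matched >= min_matched) {
          out[[length(out) + 1]] <- tibble::tibble(
            feature_a = features$feature_id[i],
            feature_b = features$feature_id[j],
            cosine = cs$cosine,
            delta_mass = a$precursor_mz - b$precursor_mz,
            n_matched = as.integer(cs$n_matched)
          )
        }
      }
    }
  }
  edges <- if (length(out) == 0) {
    tibble::tibble(feature_a = character(0), feature_b = character(0),
                   cosine = numeric(0), delta_mass = numeric(0),
                   n_matched = integer(0))
  } else dplyr::bind_rows(out)
  if (!is.null(top_k) && nrow(edges) > 0) {
    keep <- rep(TRUE, nrow(edges))
    for (node in unique(c(edges$feature_a, edges$feature_b))) {
      touch <- which(edges$feature_a == node | edges$feature_b == node)
      if (length(touch) > top_k) {
        drop <- touch[order(-edges$cosine[touch])][-seq_len(top_k)]
        keep[drop] <- FALSE
      }
    }
    edges <- edges[keep, , drop = FALSE]
  }
  edges
}

#' Export a molecular network to GraphML
#'
#' @param edges Edge tibble from [build_network()].
#' @param path Output `.graphml` path.
#' @param features Optional feature tibble; `feature_id` plus any
#'   plain columns become node attributes.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(edges, path, features = NULL) {
  verts <- if (!is.null(features)) {
    keep <- vapply(features, function(col) is.atomic(col), logical(1))
    df <- as.data.frame(features[, keep, drop = FALSE])
    names(df)[names(df) == "feature_id"] <- "name"
    df[, c("name", setdiff(names(df), "name")), drop = FALSE]
  } else NULL
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# monoisotopic homolog mass differences
HOMOLOG_DELTAS <- c(CH2 = 14.01565, C2H4 = 28.03130, H2 = 2.01565)

#' Propagate chain-length analog annotations through a network
#'
#' Neighbors of an annotated node inherit a putative (MSI level 2)
#' analog annotation when their precursor mass difference matches a
#' homolog delta (CH2, C2H4 or H2) within `frag_tol` and the
#' retention-time rule holds: longer (or more saturated) chains elute
#' later, with `rt_tol` minutes of slack. Propagation is single-hop by
#' default; nodes receiving conflicting names are flagged ambiguous.
#'
#' @param edges Edge tibble from [build_network()].
#' @param features Tibble with `feature_id`, `precursor_mz`, `rt`.
#' @param seeds Tibble with `feature_id`, `head`, `carbons`,
#'   `unsaturations` (library-matched nodes, MSI level 2 anchors).
#' @param frag_tol Mass tolerance for the homolog delta (Da).
#' @param rt_tol Retention-time slack in minutes (default 0.05).
#' @param max_hops Number of propagation rounds (default 1).
#' @return A tibble of putative annotations: `feature_id`,
#'   `annotation`, `head`, `carbons`, `unsaturations`, `via`,
#'   `msi_level` (2), `putative` (TRUE), `ambiguous`.
#' @export
propagate_annotations <- function(edges, features, seeds,
                                  frag_tol = 0.02, rt_tol = 0.05,
                                  max_hops = 1L) {
  empty <- tibble::tibble(feature_id = character(0), annotation = character(0),
                          head = character(0), carbons = integer(0),
                          unsaturations = integer(0), via = character(0),
                          msi_level = integer(0), putative = logical(0),
                          ambiguous = logical(0))
  if (nrow(seeds) == 0 || nrow(edges) == 0) return(empty)
  feat <- features
  anno <- seeds
  anno$via <- anno$feature_id
  found <- list()
  for (hop in seq_len(max_hops)) {
    new_rows <- list()
    for (s in seq_len(nrow(anno))) {
      sid <- anno$feature_id[s]
      srow <- feat[feat$feature_id == sid, ]
      if (nrow(srow) == 0) stop("seed '", sid, "' not present in the network features")
      nbrs <- unique(c(edges$feature_b[edges$feature_a == sid],
                       edges$feature_a[edges$feature_b == sid]))
      nbrs <- setdiff(nbrs, c(anno$feature_id, seeds$feature_id))
      for (nb in nbrs) {
        nrow_ <- feat[feat$feature_id == nb, ]
        delta <- nrow_$precursor_mz - srow$precursor_mz
        hit <- which(abs(abs(delta) - HOMOLOG_DELTAS) <= frag_tol)
        if (length(hit) == 0) next
        kind <- names(HOMOLOG_DELTAS)[hit[1]]
        sgn <- sign(delta)
        dc <- if (kind == "CH2") 1L * sgn else if (kind == "C2H4") 2L * sgn else 0L
        du <- if (kind == "H2") -1L * sgn else 0L   # +H2 = hydrogenation
        carbons <- anno$carbons[s] + dc
        unsat <- anno$unsaturations[s] + du
        if (carbons < 3 || unsat < 0) next
        # elution rule: longer / more saturated chains elute later
        later <- dc > 0 || (dc == 0 && du < 0)
        drt <- nrow_$rt - srow$rt
        ok <- if (later) drt > -rt_tol else drt < rt_tol
        if (!ok) next
        new_rows[[length(new_rows) + 1]] <- tibble::tibble(
          feature_id = nb,
          head = anno$head[s], carbons = carbons, unsaturations = unsat,
          via = sid
        )
      }
    }
    if (length(new_rows) == 0) break
    nr <- dplyr::bind_rows(new_rows)
    found[[hop]] <- nr
    anno <- dplyr::bind_rows(anno[, c("feature_id", "head", "carbons",
                                      "unsaturations", "via")], nr)
    anno <- anno[!duplicated(anno$feature_id), , drop = FALSE]
  }
  if (length(found) == 0) return(empty)
  res <- dplyr::bind_rows(found)
  res$annotation <- paste0(res$head, " ", tail_name(res$carbons, res$unsaturations))
  res$msi_level <- 2L
  res$putative <- TRUE
  amb <- tapply(res$annotation, res$feature_id, function(x) length(unique(x)) > 1)
  res$ambiguous <- as.logical(amb[res$feature_id])
  res[, c("feature_id", "annotation", "head", "carbons", "unsaturations",
          "via", "msi_level", "putative", "ambiguous")]
}
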