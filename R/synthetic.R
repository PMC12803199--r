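# Seeded generators for every input the pipeline consumes, with
# ground-truth manifests: head/tail tables, reaction-mixture runs,
# a repository-style corpus with metadata, and two-group feature
# tables. The fragment model is deliberately chemical-bookkeeping
# only: peaks are protonated sub-formula masses plus noise, which is
# exactly what the explanation and diagnostic gates measure.

# real amine head groups with at least one primary amine; the first
# n_heads rows are used in generated tables (order fixed)
.HEAD_POOL <- data.frame(stringsAsFactors = FALSE, matrix(ncol = 2, byrow = TRUE, c(
  "alanine",            "CC(N)C(=O)O",
  "arginine",           "NC(CCCNC(=N)N)C(=O)O",
  "asparagine",         "NC(CC(N)=O)C(=O)O",
  "aspartic acid",      "NC(CC(=O)O)C(=O)O",
  "cysteine",           "NC(CS)C(=O)O",
  "glutamic acid",      "NC(CCC(=O)O)C(=O)O",
  "glutamine",          "NC(CCC(N)=O)C(=O)O",
  "glycine",            "NCC(=O)O",
  "histidine",          "NC(Cc1c[nH]cn1)C(=O)O",
  "isoleucine",         "CCC(C)C(N)C(=O)O",
  "leucine",            "CC(C)CC(N)C(=O)O",
  "lysine",             "NCCCCC(N)C(=O)O",
  "methionine",         "CSCCC(N)C(=O)O",
  "phenylalanine",      "NC(Cc1ccccc1)C(=O)O",
  "serine",             "OCC(N)C(=O)O",
  "threonine",          "CC(O)C(N)C(=O)O",
  "tryptophan",         "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  "tyrosine",           "NC(Cc1ccc(O)cc1)C(=O)O",
  "valine",             "CC(C)C(N)C(=O)O",
  "ornithine",          "NCCCC(N)C(=O)O",
  "citrulline",         "NC(CCCNC(N)=O)C(=O)O",
  "beta-alanine",       "NCCC(=O)O",
  "GABA",               "NCCCC(=O)O",
  "5-aminovaleric acid","NCCCCC(=O)O",
  "putrescine",         "NCCCCN",
  "cadaverine",         "NCCCCCN",
  "1,3-diaminopropane", "NCCCN",
  "spermidine",         "NCCCCNCCCN",
  "agmatine",           "NCCCCNC(=N)N",
  "ethanolamine",       "NCCO",
  "ethylamine",         "CCN",
  "propylamine",        "CCCN",
  "butylamine",         "CCCCN",
  "isobutylamine",      "CC(C)CN",
  "isoamylamine",       "CC(C)CCN",
  "hexylamine",         "CCCCCCN",
  "benzylamine",        "NCc1ccccc1",
  "phenethylamine",     "NCCc1ccccc1",
  "tyramine",           "NCCc1ccc(O)cc1",
  "dopamine",           "NCCc1ccc(O)c(O)c1",
  "serotonin",          "NCCc1c[nH]c2ccc(O)cc12",
  "tryptamine",         "NCCc1c[nH]c2ccccc12",
  "histamine",          "NCCc1c[nH]cn1",
  "taurine",            "NCCS(=O)(=O)O",
  "aminoethylphosphonate", "NCCP(=O)(O)O",
  "glucosaminol",       "NC(CO)C(O)C(O)C(O)CO"
)))
names(.HEAD_POOL) <- c("name", "smiles")

#' Generator configuration
#'
#' Defaults emulate the study scale: 42 amine heads, 19 hydroxy-acid
#' tails, positive-mode adducts, a small multi-file corpus and a
#' two-group feature table. m/z jitter defaults to a third of the
#' curation fragment tolerance so planted matches survive the gates.
#'
#' @param seed Integer master seed.
#' @param n_heads,n_tails Table sizes.
#' @param noise List: `mz_sd` (Da), `int_sigma` (log-normal sigma for
#'   intensities), `n_spurious` (non-chemical peaks per spectrum).
#' @param corpus List: `n_files`, `planted_fraction`, `organs`,
#'   `taxa`, `diseases`.
#' @param effects List: `n_features`, `n_affected`, `effect_log10`,
#'   `n_per_group`, `n_blanks`, `n_contaminants`.
#' @return A named list.
#' @export
sim_config <- function(seed = 1L, n_heads = 42L, n_tails = 19L,
                       noise = list(), corpus = list(), effects = list()) {
  list(
    seed = as.integer(seed), n_heads = n_heads, n_tails = n_tails,
    noise = utils::modifyList(
      list(mz_sd = 0.003, int_sigma = 0.3, n_spurious = 3L,
           spurious_meanlog = log(200)), noise),
    corpus = utils::modifyList(
      list(n_files = 40L, planted_fraction = 0.5,
           organs = c("feces", "blood", "brain", "skin", "urine", "saliva"),
           taxa = c("9606|Homo sapiens", "10090|Mus musculus",
                    "562|Escherichia coli", "1423|Bacillus subtilis",
                    "3702|Arabidopsis thaliana"),
           diseases = c("healthy", "diabetes mellitus",
                        "inflammatory bowel disease")), corpus),
    effects = utils::modifyList(
      list(n_features = 100L, n_affected = 10L, effect_log10 = 1,
           n_per_group = 20L, n_blanks = 3L, n_contaminants = 5L), effects)
  )
}

#' Generate head and tail definition tables
#'
#' Heads are drawn in fixed order from a built-in pool of real amine
#' head groups (amino acids, polyamines, biogenic amines); several
#' carry two primary amines. Diagnostic fragments are the protonated
#' head and its water loss, rounded to 4 decimals. Tails are linear
#' 3-hydroxy acids C3..C18 plus unsaturated variants.
#'
#' @param n_heads Number of heads (max 46, the built-in pool size).
#' @param n_tails Number of tails (max 22).
#' @param seed Unused for content (tables are deterministic) but kept
#'   for interface uniformity.
#' @param dir Optional directory; when given, `heads.tsv` and
#'   `tails.tsv` are written there.
#' @return A list with `heads` and `tails` tibbles (parsed form).
#' @export
generate_heads_tails <- function(n_heads = 42L, n_tails = 19L, seed = 1L,
                                 dir = NULL) {
  stopifnot(n_heads >= 1, n_tails >= 1)
  if (n_heads > nrow(.HEAD_POOL)) {
    stop("at most ", nrow(.HEAD_POOL), " built-in head groups available")
  }
  pool <- .HEAD_POOL[seq_len(n_heads), , drop = FALSE]
  diag <- vapply(pool$smiles, function(s) {
    mh <- monoisotopic_mass(mol_formula(s)) + PROTON_MASS
    paste(sprintf("%.4f", c(mh, mh - WATER_MASS)), collapse = ";")
  }, character(1))
  heads <- heads_from_rows(pool$name, pool$smiles, unname(diag))

  sat <- 3:18
  unsat <- cbind(c(10, 14, 18, 8, 12, 16), 1)
  spec <- rbind(cbind(sat, 0), unsat)
  if (n_tails > nrow(spec)) stop("at most ", nrow(spec), " built-in tails available")
  spec <- spec[seq_len(n_tails), , drop = FALSE]
  tails <- tails_from_rows(
    tail_name(spec[, 1], spec[, 2]),
    vapply(seq_len(nrow(spec)), function(i) hydroxy_tail_smiles(spec[i, 1], spec[i, 2]),
           character(1)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tibble::tibble(name = pool$name, smiles = pool$smiles,
                                    diagnostic_fragments = unname(diag)),
                     file.path(dir, "heads.tsv"))
    readr::write_tsv(tails[, c("name", "smiles")], file.path(dir, "tails.tsv"))
  }
  list(heads = heads, tails = tails)
}

# strictly-ascending peak matrix from possibly colliding m/z values
.make_peaks <- function(mz, intensity) {
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  while (length(mz) > 1 && any(diff(mz) <= 0)) {
    i <- which(diff(mz) <= 0)[1] + 1
    mz[i] <- mz[i - 1] + 1e-6
    o2 <- order(mz); mz <- mz[o2]; intensity <- intensity[o2]
  }
  list(mz = mz, intensity = intensity)
}

#' Simulate the MS2 spectrum of one conjugate
#'
#' Peaks are (i) the head-group diagnostic fragments, (ii) protonated
#' head and conjugate sub-formula fragments (water losses, the acyl
#' fragment), all jittered by `mz_sd`, plus (iii) `n_spurious`
#' uniform-random peaks at non-chemical mass defects. The planted
#' explained-intensity fraction is recorded in the `truth` attribute.
#'
#' @param target One row of a target tibble.
#' @param head Matching row of the head table.
#' @param adduct Adduct name (sets the precursor m/z).
#' @param noise Noise list from [sim_config()].
#' @param seed Integer seed.
#' @param rt,provenance Passed to the spectrum.
#' @return A `spectrum`; attribute `truth` holds
#'   `explained_fraction`.
#' @export
simulate_conjugate_spectrum <- function(target, head, adduct = "[M+H]+",
                                        noise = sim_config()$noise, seed = 1L,
                                        rt = NA_real_, provenance = NA_character_) {
  set.seed(seed)
  M <- target$mono_mass
  prec <- adduct_mz(M, adduct)
  mh <- head$mono_mass + PROTON_MASS
  frag_mz <- c(head$diagnostic_fragments[[1]],
               mh, mh - WATER_MASS,
               M + PROTON_MASS, M + PROTON_MASS - WATER_MASS,
               M - head$mono_mass + PROTON_MASS)  # acyl-derived fragment
  frag_mz <- unique(round(frag_mz, 5))
  frag_mz <- frag_mz[frag_mz > 50]
  n_chem <- length(frag_mz)
  chem_int <- stats::rlnorm(n_chem, meanlog = log(5e3), sdlog = noise$int_sigma) *
    c(rep(2, min(2, n_chem)), rep(1, max(0, n_chem - 2)))
  n_sp <- noise$n_spurious
  sp_mz <- if (n_sp > 0) {
    floor(stats::runif(n_sp, 60, max(120, prec - 20))) + stats::runif(n_sp, 0.4, 0.6)
  } else numeric(0)
  sp_meanlog <- if (is.null(noise$spurious_meanlog)) log(200) else noise$spurious_meanlog
  sp_int <- if (n_sp > 0) {
    stats::rlnorm(n_sp, meanlog = sp_meanlog, sdlog = noise$int_sigma)
  } else numeric(0)
  jit <- stats::rnorm(n_chem, 0, noise$mz_sd)
  pk <- .make_peaks(c(frag_mz + jit, sp_mz), c(chem_int, sp_int))
  sp <- new_spectrum(pk$mz, pk$intensity, ms_level = 2L,
                     precursor_mz = prec, rt = rt, provenance = provenance)
  attr(sp, "truth") <- list(
    explained_fraction = sum(chem_int) / sum(chem_int, sp_int))
  sp
}

# a pure-noise MS2 spectrum at non-chemical mass defects
.noise_spectrum <- function(precursor_mz, n_peaks = 8, rt = NA_real_,
                            provenance = NA_character_) {
  mz <- floor(stats::runif(n_peaks, 60, max(150, precursor_mz - 10))) +
    stats::runif(n_peaks, 0.4, 0.6)
  pk <- .make_peaks(mz, stats::rlnorm(n_peaks, log(1e3), 0.5))
  new_spectrum(pk$mz, pk$intensity, ms_level = 2L, precursor_mz = precursor_mz,
               rt = rt, provenance = provenance)
}

#' Simulate one reaction-mixture LC-MS/MS run
#'
#' Each planned (target, adduct) pair becomes a Gaussian MS1
#' extracted-ion trace with the planned apex height plus linked MS2
#' scans near the apex. The default plan detects each target with
#' probability `detection_prob`, always planting the protonated form
#' for detected targets and extra adducts at random; pass `plan` to
#' place features above or below the intensity floors deliberately.
#'
#' @param targets Target tibble.
#' @param heads Head table.
#' @param seed Integer seed.
#' @param detection_prob Per-target detection probability (default
#'   0.85).
#' @param plan Optional tibble (`target_id`, `adduct`, `apex_height`,
#'   `n_ms2`) overriding the random plan.
#' @param noise Noise list from [sim_config()].
#' @param file Run name used in provenance strings.
#' @return A list: `run` (list with `file`, `ms1`, `ms2`) and `truth`
#'   (the realized plan with per-entry expected gate outcomes).
#' @export
simulate_reaction_run <- function(targets, heads, seed = 1L,
                                  detection_prob = 0.85, plan = NULL,
                                  noise = sim_config()$noise,
                                  file = "reaction_01") {
  stopifnot(nrow(targets) > 0)
  set.seed(seed)
  if (is.null(plan)) {
    rows <- list()
    for (t in seq_len(nrow(targets))) {
      if (stats::runif(1) > detection_prob) next
      adducts <- "[M+H]+"
      for (extra in c("[M+Na]+", "[M+NH4]+", "[M-H2O+H]+", "[M+K]+")) {
        if (stats::runif(1) < 0.3) adducts <- c(adducts, extra)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        target_id = targets$target_id[t], adduct = adducts,
        apex_height = stats::rlnorm(length(adducts), log(8e5), 0.5),
        n_ms2 = 1L + stats::rbinom(length(adducts), 1, 0.3))
    }
    plan <- if (length(rows) > 0) dplyr::bind_rows(rows) else
      tibble::tibble(target_id = character(0), adduct = character(0),
                     apex_height = numeric(0), n_ms2 = integer(0))
  }
  rt_grid <- seq(0.05, 10, by = 0.1)
  sigma <- 0.12
  ms1_mz <- vector("list", length(rt_grid))
  ms1_int <- vector("list", length(rt_grid))
  ms2 <- list()
  truth_rows <- list()
  if (nrow(plan) > 0) {
    plan$apex_rt <- stats::runif(nrow(plan), 1, 9)
    for (p in seq_len(nrow(plan))) {
      t <- match(plan$target_id[p], targets$target_id)
      h <- match(targets$head[t], heads$name)
      theo <- adduct_mz(targets$mono_mass[t], plan$adduct[p])
      trace <- plan$apex_height[p] *
        exp(-(rt_grid - plan$apex_rt[p])^2 / (2 * sigma^2))
      on_scan <- trace >= pmax(1, plan$apex_height[p] * 1e-3)
      for (i in which(on_scan)) {
        # mass jitter in ppm so the 10 ppm XIC window holds at any m/z
        ms1_mz[[i]] <- c(ms1_mz[[i]], theo * (1 + stats::rnorm(1, 0, 1.5e-6)))
        ms1_int[[i]] <- c(ms1_int[[i]], trace[i])
      }
      ms2_rts <- plan$apex_rt[p] + stats::runif(plan$n_ms2[p], -0.05, 0.05)
      for (r in ms2_rts) {
        scan <- length(ms2) + 1L
        sp <- simulate_conjugate_spectrum(
          targets[t, ], heads[h, ], plan$adduct[p], noise,
          seed = seed + 7919L * scan, rt = r,
          provenance = paste0(file, ":", scan))
        # precursor observed near the apex trace, jitter well within 10 ppm
        sp$precursor_mz <- theo * (1 + stats::rnorm(1, 0, 1.5e-6))
        ms2[[scan]] <- sp
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          target_id = plan$target_id[p], adduct = plan$adduct[p], scan = scan,
          apex_height = plan$apex_height[p],
          explained_fraction = attr(sp, "truth")$explained_fraction)
      }
    }
  }
  ms1 <- lapply(seq_along(rt_grid), function(i) {
    if (is.null(ms1_mz[[i]])) {
      new_spectrum(numeric(0), numeric(0), ms_level = 1L, rt = rt_grid[i])
    } else {
      pk <- .make_peaks(ms1_mz[[i]], ms1_int[[i]])
      new_spectrum(pk$mz, pk$intensity, ms_level = 1L, rt = rt_grid[i])
    }
  })
  truth <- if (length(truth_rows) > 0) dplyr::bind_rows(truth_rows) else
    tibble::tibble(target_id = character(0), adduct = character(0),
                   scan = integer(0), apex_height = numeric(0),
                   explained_fraction = numeric(0))
  list(run = list(file = file, ms1 = ms1, ms2 = ms2), truth = truth)
}

#' Simulate a repository-style corpus with metadata
#'
#' Planted files embed noisy copies of library spectra (the generator
#' verifies raw cosine >= 0.9 against the original, regenerating with
#' reduced jitter when needed); decoy files contain peaks at
#' non-chemical mass defects, verified to share fewer than 3
#' coincident ions with every library spectrum. Every file gets
#' taxonomy / body-part / disease metadata from the configured pools,
#' plus a small number of blank files.
#'
#' @param library_query Query table from [library_query_table()].
#' @param config From [sim_config()] (uses `corpus` and `noise`).
#' @param seed Integer seed.
#' @return A list: `corpus` (tibble for [fasst_search()]), `metadata`
#'   tibble, `truth` (planted matches with their metadata).
#' @export
simulate_repository <- function(library_query, config = sim_config(), seed = 1L) {
  stopifnot(nrow(library_query) > 0)
  set.seed(seed)
  cc <- config$corpus
  n_planted <- round(cc$n_files * cc$planted_fraction)
  files <- list()
  meta_rows <- list()
  truth_rows <- list()
  lib_peaks <- lapply(library_query$spectrum, function(s) s$peaks[, "mz"])
  for (f in seq_len(cc$n_files)) {
    fname <- sprintf("corpus_%03d", f)
    planted <- f <= n_planted
    organ <- sample(cc$organs, 1)
    taxon <- sample(cc$taxa, 1)
    disease <- sample(cc$diseases, 1)
    sps <- list()
    if (planted) {
      picks <- sample(nrow(library_query), sample(1:3, 1), replace = FALSE)
      for (q in picks) {
        orig <- library_query$spectrum[[q]]
        sd_try <- config$noise$mz_sd
        for (try in 1:20) {
          pk <- .make_peaks(orig$peaks[, "mz"] + stats::rnorm(n_peaks(orig), 0, sd_try),
                            orig$peaks[, "intensity"] *
                              stats::rlnorm(n_peaks(orig), 0, 0.2))
          cand <- new_spectrum(pk$mz, pk$intensity, ms_level = 2L,
                               precursor_mz = orig$precursor_mz +
                                 stats::rnorm(1, 0, 0.003),
                               rt = stats::runif(1, 0.5, 9.5))
          if (raw_cosine(cand, orig, 0.02)$cosine >= 0.9 &&
              abs(cand$precursor_mz - orig$precursor_mz) <= 0.01) break
          sd_try <- sd_try / 2
        }
        scan <- length(sps) + 1L
        cand$provenance <- paste0(fname, ":", scan)
        sps[[scan]] <- cand
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          corpus_file = fname, scan = scan,
          query_id = library_query$query_id[q],
          name = library_query$name[q],
          head = library_query$head[q], tail = library_query$tail[q],
          taxonomy = taxon, body_part = organ, disease = disease)
      }
    } else {
      for (s in seq_len(sample(2:4, 1))) {
        prec <- sample(library_query$spectrum, 1)[[1]]$precursor_mz +
          stats::runif(1, -0.015, 0.015)
        for (try in 1:50) {
          cand <- .noise_spectrum(prec, n_peaks = 8,
                                  rt = stats::runif(1, 0.5, 9.5),
                                  provenance = paste0(fname, ":", s))
          coincident <- max(vapply(lib_peaks, function(mzs) {
            sum(vapply(cand$peaks[, "mz"], function(m) any(abs(mzs - m) <= 0.02),
                       logical(1)))
          }, numeric(1)))
          if (coincident < 3) break
        }
        sps[[s]] <- cand
      }
    }
    files[[fname]] <- sps
    meta_rows[[f]] <- tibble::tibble(
      filename = fname, NCBITaxonomy = taxon, UBERONBodyPartName = organ,
      DOIDCommonName = disease, SampleType = "sample")
  }
  for (b in 1:2) {
    fname <- sprintf("blank_%02d", b)
    files[[fname]] <- list(.noise_spectrum(stats::runif(1, 200, 400),
                                           provenance = paste0(fname, ":1")))
    meta_rows[[length(meta_rows) + 1]] <- tibble::tibble(
      filename = fname, NCBITaxonomy = "missing", UBERONBodyPartName = "missing",
      DOIDCommonName = "missing", SampleType = "blank")
  }
  metadata_raw <- dplyr::bind_rows(meta_rows)
  truth <- if (length(truth_rows) > 0) dplyr::bind_rows(truth_rows) else
    tibble::tibble(corpus_file = character(0), scan = integer(0),
                   query_id = character(0), name = character(0),
                   head = character(0), tail = character(0),
                   taxonomy = character(0), body_part = character(0),
                   disease = character(0))
  list(
    corpus = corpus_table(files),
    metadata = tibble::tibble(
      file_id = metadata_raw$filename, taxonomy = metadata_raw$NCBITaxonomy,
      body_part = metadata_raw$UBERONBodyPartName,
      disease = metadata_raw$DOIDCommonName,
      sample_role = tolower(metadata_raw$SampleType)),
    metadata_raw = metadata_raw,
    truth = truth
  )
}

#' Simulate a two-group feature table with planted effects
#'
#' Unaffected features share a log-normal area distribution across
#' both groups; affected features are depleted in group A by the
#' configured log10 effect; contaminant features are high in blanks.
#'
#' @param config From [sim_config()] (uses `effects`).
#' @param seed Integer seed.
#' @param groups Two group labels (default `c("case", "control")`).
#' @return A list: `table` (a `feature_table`) and `truth` (affected
#'   feature ids with direction, contaminant ids).
#' @export
simulate_feature_table <- function(config = sim_config(), seed = 1L,
                                   groups = c("case", "control")) {
  set.seed(seed)
  ef <- config$effects
  stopifnot(ef$n_per_group >= 3)
  n_f <- ef$n_features + ef$n_contaminants
  ids <- sprintf("F%04d", seq_len(n_f))
  samples <- tibble::tibble(
    sample_id = c(sprintf("%s_%02d", groups[1], seq_len(ef$n_per_group)),
                  sprintf("%s_%02d", groups[2], seq_len(ef$n_per_group)),
                  sprintf("blank_%02d", seq_len(ef$n_blanks))),
    group = c(rep(groups[1], ef$n_per_group), rep(groups[2], ef$n_per_group),
              rep("blank", ef$n_blanks)),
    role = c(rep("sample", 2 * ef$n_per_group), rep("blank", ef$n_blanks))
  )
  meanlog <- stats::rnorm(n_f, log(1e5), 0.8)
  areas <- matrix(0, n_f, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    areas[, j] <- stats::rlnorm(n_f, meanlog, 0.5)
  }
  affected <- if (ef$n_affected > 0) seq_len(ef$n_affected) else integer(0)
  ia <- samples$group == groups[1]
  areas[affected, ia] <- areas[affected, ia] * 10^(-ef$effect_log10)
  contam <- if (ef$n_contaminants > 0) ef$n_features + seq_len(ef$n_contaminants) else integer(0)
  ib <- samples$role == "blank"
  areas[, ib] <- areas[, ib] * 0.01          # real features nearly absent in blanks
  areas[contam, ] <- stats::rlnorm(length(contam) * nrow(samples), log(5e4), 0.3)
  features <- tibble::tibble(
    feature_id = ids,
    mz = stats::runif(n_f, 150, 600),
    rt = stats::runif(n_f, 0.5, 9.5),
    drift = stats::runif(n_f, 0.6, 1.3)
  )
  list(
    table = feature_table(features, samples, areas),
    truth = list(affected = ids[affected], direction = rep("depleted_in_A", length(affected)),
                 contaminants = ids[contam])
  )
}

#' Simulate a complete study end to end
#'
#' Composes the generators: head/tail tables, conjugate enumeration,
#' reaction runs, library construction, repository corpus with
#' metadata, and a feature table — the full desk-scale stand-in for
#' the study's instruments and repositories.
#'
#' @param config From [sim_config()].
#' @param n_runs Number of reaction-mixture runs (targets split
#'   across runs).
#' @return A list with `tables`, `targets`, `runs`, `library`,
#'   `repository`, `features` and the per-stage truth manifests.
#' @export
simulate_study <- function(config = sim_config(), n_runs = 2L) {
  st <- generate_heads_tails(config$n_heads, config$n_tails, config$seed)
  targets <- enumerate_conjugates(st$heads, st$tails)
  idx <- split(seq_len(nrow(targets)),
               rep(seq_len(n_runs), length.out = nrow(targets)))
  runs <- lapply(seq_len(n_runs), function(r) {
    simulate_reaction_run(targets[idx[[r]], ], st$heads,
                          seed = config$seed + 101L * r,
                          noise = config$noise,
                          file = sprintf("reaction_%02d", r))
  })
  lib <- build_library(lapply(runs, `[[`, "run"), targets, st$heads)
  lq <- library_query_table(lib)
  repo <- simulate_repository(lq, config, seed = config$seed + 997L)
  feats <- simulate_feature_table(config, seed = config$seed + 1009L)
  list(tables = st, targets = targets, runs = runs, library = lib,
       repository = repo, features = feats)
}
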