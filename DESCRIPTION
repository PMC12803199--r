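Package: revamide
Title: Reverse Metabolomics of 3-Hydroxy N-Acyl Amides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesis-driven reverse-metabolomics workflow for 3-hydroxy
    N-acyl amide lipids: combinatorial enumeration of amine head x
    hydroxy fatty-acid tail amide conjugates with adduct mass arithmetic,
    extraction and validation of reference MS2 spectra from
    reaction-mixture LC-MS/MS runs, cosine-based library-versus-repository
    spectral search with molecular networking and annotation propagation,
    joins against harmonized sample metadata with head x tail aggregation
    surfaces, and feature-table statistics (blank filtering, Wilcoxon
    rank-sum group comparisons, MSI confidence assignment). Seeded
    synthetic-data generators with ground-truth manifests stand in for
    instruments and public repositories so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    igraph,
    stats,
    utils
Suggests:
    mzR,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
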