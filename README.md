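# revamide

Reverse metabolomics of 3-hydroxy *N*-acyl amides in R.

3-hydroxy *N*-acyl amides — conjugates of an amine "head" (amino acids,
polyamines, biogenic amines) with a β-hydroxylated fatty-acid "tail"
through an amide bond — are bioactive microbial/host lipids that go
largely unannotated in untargeted LC-MS/MS studies because reference MS2
spectra are scarce. The reverse-metabolomics strategy closes that gap
from the other direction: synthesize the candidate molecules
combinatorially, curate their MS2 spectra into a reference library, and
search that library across public data repositories to discover where
the molecules occur and what biology they track.

`revamide` implements the complete computational side of that workflow
for metabolomics researchers:

1. **Conjugate enumeration** — all head × tail amides from TSV
   definition tables, assembled at the molecular-graph level (SMILES in,
   SMILES out), with neutral formulas, monoisotopic masses and adducted
   m/z values ([M+H]⁺, [M+Na]⁺, [M+K]⁺, [M+NH4]⁺, [M−H2O+H]⁺). A head
   with *k* primary amines yields *k* positional isomers per tail.
2. **Targeted library building** — extraction of candidate MS2 spectra
   from reaction-mixture runs (±10 ppm XIC features, MS1 ≥ 5×10⁴,
   feature height ≥ 10⁵), validated by an MS2 explanation score
   (explained-intensity fraction over protonated sub-formulas, gate
   0.6), head-group diagnostic fragments, and an adduct-inclusion rule
   anchored on [M+H]⁺/[M+NH4]⁺.
3. **Spectral search** — raw and modified cosine with exact
   maximum-weight peak assignment, MASST/FASST-style batch search
   (precursor/fragment tolerance 0.02 Da, cosine ≥ 0.7, ≥ 3 matched
   ions), molecular networking (≥ 2 matched peaks) and chain-length
   analog annotation propagation (CH2/C2H4/H2 deltas + elution rule).
4. **Metadata aggregation** — joins to ReDU-style harmonized metadata,
   three-state head × tail presence matrices, per-taxon/organ/disease
   tallies, and chain parity/saturation summaries.
5. **Downstream statistics** — blank filtering, Wilcoxon rank-sum group
   comparisons (exact at small n), time trends, and MSI confidence
   levels from retention-time + ion-mobility agreement with standards.
6. **Synthetic data** — seeded generators with ground-truth manifests
   for every input (reaction runs, repository corpora, metadata, feature
   tables), so the entire pipeline is testable without downloads.

For spectral similarity the package scores cosine similarity between
square-root-weighted peak vectors,

    cos(A, B) = Σ_(i,j)∈M √(a_i·b_j) / (‖√a‖·‖√b‖),

where M is the exact maximum-total-score one-to-one assignment of peaks
within the fragment tolerance; the modified cosine additionally allows
pairs offset by the precursor mass difference.

## Worked example

```r
library(revamide)
library(dplyr)

# study-scale tables: 42 amine heads x 19 hydroxy-acid tails
st <- generate_heads_tails(n_heads = 42, n_tails = 19)
tg <- enumerate_conjugates(st$heads, st$tails)
nrow(unique(tg[, c("head", "tail")]))   # 798 distinct head-tail pairs
nrow(tg)                                # 912 targets incl. positional isomers

# simulate one reaction-mixture run for 20 targets and build the library
sim <- simulate_reaction_run(tg[1:20, ], st$heads, seed = 11)
lib <- build_library(list(sim$run), tg[1:20, ], st$heads)
lib
#> <spectral_library: 58 accepted / 58 candidate spectra; 19 unique compounds>

# search the library against a simulated 20-file repository and aggregate
lq   <- library_query_table(lib)
repo <- simulate_repository(lq, sim_config(seed = 11, corpus = list(n_files = 20)),
                            seed = 12)
m    <- fasst_search(lq, repo$corpus)          # 41 matches at cosine >= 0.7
ann  <- join_matches(left_join(m, lq[, c("query_id", "head", "tail")],
                               by = "query_id"), repo$metadata)
presence_and_counts(ann, lq)$by_body_part
#> # A tibble: 6 x 4
#>   group  n_matches n_unique_compounds n_files
#>   <chr>      <int>              <int>   <int>
#> 1 blood         11                  5       2
#> 2 brain          9                  5       2
#> 3 feces          8                  5       2
#> 4 saliva         5                  3       1
#> 5 skin           1                  1       1
#> 6 urine          7                  5       2
```

The match counts per body part equal the generator's planted histogram;
`n_unique_compounds` collapses adducts and isomers of the same
head × tail pair.

A thin command-line dispatcher mirrors the same steps
(`enumerate`, `search`, `network`, `aggregate`, `compare`, `confirm`,
`simulate`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "revamide", package = "revamide"))')
Rscript $CLI enumerate --heads heads.tsv --tails tails.tsv --out targets.tsv
Rscript $CLI search --library library.mgf --corpus corpus/ --out matches.tsv
```

See `vignettes/revamide-methods.Rmd` for the modelling choices,
parameter defaults, and what the synthetic generators do and do not
emulate.

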