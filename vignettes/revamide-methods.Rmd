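---
title: "Methods and design notes for revamide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for revamide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revamide)
```

`revamide` implements the computational half of a synthesis-driven
reverse-metabolomics workflow for 3-hydroxy *N*-acyl amides: enumerate
the combinatorial amide targets, curate an MS2 reference library from
reaction-mixture LC-MS/MS runs, search that library across a spectral
corpus, join hits to harmonized sample metadata, and run the downstream
group statistics. This vignette records the models, the parameters that
matter, and the design decisions taken where more than one defensible
choice existed.

## Conjugate enumeration

A target is the condensation product of an amine head group and a
3-hydroxy fatty acid: formula(conjugate) = formula(head) +
formula(tail) − H2O. Assembly is done on molecular graphs, not strings:
the head and tail SMILES are parsed into atom/bond graphs, the acid
hydroxyl oxygen is deleted, the selected amine nitrogen is bonded to
the carbonyl carbon, and a fresh SMILES is written from the merged
graph. Every assembled structure is re-parsed and checked against the
elemental bookkeeping, so a malformed assembly cannot propagate
silently.

A *primary amine* (conjugation site) is a non-aromatic, uncharged
nitrogen with exactly two hydrogens bonded to a single carbon,
excluding amide nitrogens (carbon bears C=O) and guanidino nitrogens
(carbon bears C=N plus a second nitrogen). Aromatic ring NH — the
imidazole of histamine, the indole of tryptophan — is never a site.
Heads with *k* sites expand to *k* positional isomers per tail, which
share formula and mass exactly; heads with no usable site are rejected
at parse time with their row number rather than silently skipped. The
isomer policy is deliberately left to the head table: the number of
targets is exactly `sum(n_primary_amines) * n_tails`, and any further
isomer forms a laboratory might register must be encoded as extra rows.

Monoisotopic element masses are hard-coded CODATA/NIST values at 8
decimal places. Six decimals would be enough for any single atom but
not for 30-atom sums, where truncation error accumulates to ~1e-6 Da
and would defeat the package's own 1e-6 mass-conservation invariant.
Adduct mass deltas are fixed single-proton conventions with the
electron mass folded in: +1.007276 (H), +22.989218 (Na), +38.963158
(K), +18.033823 (NH4), −17.003289 (water loss), all singly charged.

Tail names follow the `3OH-Cn:m` convention (n carbons, m
unsaturations). The SMILES column of a tail table is authoritative for
structure — the name only encodes counts and is validated against the
formula CnH(2n−2m)O3. Generated tails place double bonds from carbon 5
upward at alternating positions; the choice is arbitrary (mass and
name are position-blind) but fixed, so outputs are deterministic.

## Library curation gates

Candidate extraction mirrors a targeted formula search: an
extracted-ion chromatogram at each adducted target m/z (±10 ppm), a
deliberately simple feature finder (contiguous non-zero XIC segments,
minimum width 0.2 min, feature height = segment maximum), and one
candidate per (target, adduct, MS2 scan) whose precursor falls within
the ppm window and whose retention time lies inside a feature. Floors
of 5e4 (MS1 intensity at the MS2 trigger) and 1e5 (feature height)
reject weak features.

The **MS2 explanation score** is the fraction of total fragment
intensity assignable to a protonated sub-formula of the parent within
0.01 Da. Sub-formulas are enumerated exhaustively over the
element-count grid — exact, and cheap below C60 — restricted to
valence-feasible compositions (at least one heavy atom, H ≤ 2C + N +
2). Without that restriction the sub-formula mass grid of a C20+
parent becomes dense enough (tens of masses per Da) that random noise
peaks are "explained" and the gate stops discriminating; the
restriction removes only compositions no fragment ion can have. The
acceptance threshold is 0.6. The score is an explained-intensity
fraction, not a cosine against predicted spectra; where an upstream
description of this step reads as a fragment-level cosine, we kept the
gate's role (separating structure-consistent spectra from noise) and
documented the interpretation here rather than guessing at an
unpublished predictor. A slot for external-tool verdicts (fragmentation
trees and the like) is out of scope for the in-repo pipeline.

**Diagnostic fragments** are curated per head (e.g. the glutamic-acid
trio 84.04 / 102.06 / 130.05). The default policy requires *all*
listed fragments within 0.01 Da — matching the curation example where
every consensus peak had to be present — with `min_diag` available to
relax it. Heads without curated fragments pass vacuously but are
flagged `uncurated`. This gate is also what keeps exact isobars apart:
homologous head series (glycine + Cn equals alanine + Cn−1 in formula
and therefore in every mass-derived quantity) can only be told apart
by head-specific fragments.

The **adduct-inclusion rule** keeps a sodiated, potassiated or
water-loss entry only when the same target also has an accepted
[M+H]⁺ or [M+NH4]⁺ entry; anchors are never removed. The audit table
labels every rejected candidate with the first failing gate, in the
fixed order MS1 intensity → feature height → explanation → diagnostics
→ adduct inclusion, so candidates always equal accepted plus rejected.

The fragment tolerance for explanation/diagnostics (0.01 Da) is
tighter than the 0.02 Da search tolerance because reference spectra
come from high-resolution instruments; both are configurable.

## Spectral similarity and search

Peak pairing is an exact maximum-total-score one-to-one assignment on
the tolerance-feasible bipartite graph, solved per connected component
by memoized bitmask recursion (components of real spectrum pairs are
tiny). Greedy pairing — the shortcut many tools take — is not used, so
the oracle property (equality with brute-force enumeration) holds to
machine precision. Ties in total score break toward smaller summed
|Δm/z|, then lower peak index: results are deterministic. Intensities
are square-root weighted before normalization (the common repository
convention); raw weighting is available. Degenerate all-zero-intensity
spectra are an error, not a zero.

The modified cosine additionally admits pairs offset by the precursor
mass difference; because its feasible-pair set is a superset of the
raw one and the assignment is exact, modified ≥ raw always holds. No
peak preprocessing (precursor-window removal, top-N filtering) is
applied by default since repository tools differ; both are easy to add
upstream of the search call.

Batch search gates are precursor and fragment tolerance 0.02 Da, raw
cosine ≥ 0.7, ≥ 3 matched ions. The sorted-array precursor index is a
pure pruning device: its probe window equals the precursor tolerance,
so the indexed result set provably equals the all-pairs scan (and is
tested to). Molecular networking uses the modified cosine with a
2-matched-peak minimum — short-chain conjugates and alkali adducts
genuinely have very few fragments — and annotation propagation walks
single hops from library-matched seeds along homolog mass deltas
(CH2 14.01565, C2H4 28.0313, H2 2.01565) with an elution rule: longer
or more saturated chains must not elute earlier than the seed by more
than 0.05 min. Propagated annotations are always MSI level 2 and
flagged putative; conflicting names on one node are all recorded and
the node marked ambiguous.

## Metadata aggregation

Matches join to ReDU-style metadata by normalized file identifier
(directory and extension stripped); unknown files become explicit
`unannotated` rows — no match is ever dropped. The head × tail
presence matrix is three-state (`no_spectrum` / `no_match` /
`matched`) so "we had no reference spectrum" is never conflated with
"we searched and found nothing"; counts are undefined (NA), zero, or
positive in the three states respectively. "Unique compound" always
means a distinct head × tail pair, collapsing adducts, isomers and
water-loss entries; spectrum-level and compound-level counters are
reported side by side. Report percentages round half away from zero to
integers (machine-precision values stay in the tables).

## Downstream statistics

Blank filtering retains a feature when mean(sample areas) ≥ ratio ×
max(mean blank areas, ε): ratio 3 and ε = 1 area unit by default, both
prominent in the interface because the conventional contamination cut
is practice, not physics. The Wilcoxon rank-sum test delegates to
`stats::wilcox.test`, exact for tie-free samples when the smaller
group has ≤ 8 observations, normal approximation with tie and
continuity correction otherwise; an independent permutation-
enumeration oracle in the test suite pins the exact branch. Group
comparisons report log10 fold changes on ε-stabilized means and use
raw p < 0.05 by default — matching the reanalysis convention the
workflow follows — with Benjamini–Hochberg as an explicit opt-in.
Longitudinal series get both a first-versus-last-bin rank-sum contrast
and a Spearman rank correlation, clearly labeled, because the trend
test behind "significantly increasing with time" claims is typically
unnamed; we report both rather than fold one into the other.

MSI confidence: level 1 requires an accepted MS2 match *plus*
retention time within 0.1 min *and* drift time (1/K0) within 0.02
V·s/cm² of an authentic standard; anything less — missing standard,
missing drift, tolerance miss — stays level 2 with the reason
recorded. A feature without an MS2 match is never upgraded. The RT and
drift tolerances are defaults chosen at the scale of modern UHPLC/TIMS
reproducibility, not published constants; override them per study.

## Synthetic data: what it does and does not emulate

The generators produce every input the pipeline consumes, each with a
ground-truth manifest, under a single integer seed (byte-identical
reruns). The head pool is 46 real amines; the default configuration
(42 heads × 19 tails: C3–C18 saturated plus six unsaturated) matches
the combinatorial scale of the laboratory workflow, and the noise
defaults (m/z jitter 0.003 Da for fragments, ppm-scaled for
precursors, log-normal intensity scatter σ = 0.3, 3 spurious peaks per
spectrum) sit well inside the curation tolerances so that planted
truth survives the gates by construction — that calibration is the
point, since the acceptance checks compare pipeline output to planted
truth.

Fragmentation is chemical bookkeeping, not physics: planted peaks are
protonated sub-formula masses (head, head − H2O, conjugate ± H2O, the
acyl fragment) plus uniform spurious peaks at non-chemical mass
defects. That is exactly the structure the explanation and diagnostic
gates measure, which makes generator guarantees checkable at
generation time (planted repository copies are verified to keep raw
cosine ≥ 0.9 against their originals; decoy spectra are verified to
share < 3 coincident ions with every library spectrum) — so the
downstream tests are sound rather than circular. What the generator
does **not** emulate: chromatographic peak shapes beyond a Gaussian
trace, isotope envelopes, chimeric MS2, instrument-specific
fragmentation energetics, negative mode, and real repository metadata
sparsity. Passing the end-to-end tests therefore demonstrates that the
pipeline's logic is correct under its stated tolerances, not that any
particular real-data recall will be achieved.

Problem sizes in the shipped tests were chosen to exercise every code
path at desk scale: ~200-spectrum corpora for search completeness, 50
seeded corpora for gate monotonicity, 10,000 null features (n = 20 per
group) for the type-I error band [0.04, 0.06] at α = 0.05, 1,000
random ≤ 8-peak pairs for the cosine oracle, and an 8 × 6 head × tail
end-to-end recovery.

## Known limitations

* SMILES support covers the organic subset plus bracket atoms over
  C/H/N/O/S/P/Na/K — sufficient for amine heads and acyl tails, not a
  general cheminformatics parser; stereochemistry is accepted and
  ignored (the S-configuration of the natural compounds is out of
  scope).
* Exact isobars within a homologous series are indistinguishable by
  mass and precursor; the diagnostic-fragment gate is the only
  separator, so heads without curated fragments can cross-assign.
* The feature finder is intentionally minimal; real studies should
  import tables from a dedicated feature finder and use
  `read_feature_csv()`.
* Repository-scale counts from the original resource (hundreds of
  thousands of matches across tens of thousands of files) depend on
  live public repositories and are shipped only as static summary
  tables for bookkeeping checks; the package reproduces the method,
  not the repository.
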