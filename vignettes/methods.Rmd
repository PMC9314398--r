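---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMetamorph)
```

scMetamorph implements the post-quantification statistics needed to analyse
a droplet single-cell atlas sampled across amphibian metamorphosis: ambient
RNA correction, Jensen–Shannon TF specificity, cross-stage driver-TF
scoring, and a four-module gene-trajectory procedure, together with a
synthetic atlas generator that plants all of this structure so each stage is
validated by parameter recovery. This vignette records the models, their
assumptions, and the choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## Ambient background correction

**Model.** Microwell/droplet libraries capture cell-free RNA released during
lysis and washing alongside each cell's own transcripts. Barcodes with fewer
than 500 UMIs are assumed to be empty beads exposed only to that ambient
pool, so their per-gene mean `bg(g)` (per batch) estimates the ambient
profile at bead scale. A cell carries the same contamination scaled by an
unknown per-cell factor; it is estimated as the **median of the per-gene
fold differences** `count(c,g)/bg(g)` over genes with `bg(g) > 0`. The
background `round(bg(g) · s(c))` is subtracted with clipping at zero, so the
corrected matrix stays integer-valued inside `[0, observed]`.

**Assumptions and consequences.** The median-fold estimator presumes that
*most background genes are not part of the cell's own program*: for such
genes the fold ratio reflects pure contamination, and the median lands among
them. When a majority of detected background genes are endogenously
expressed, the median drifts toward the cell's total-count ratio and the
correction over-subtracts. This is why the estimator is run per batch on the
*unfiltered* matrix, and why the synthetic generator gives each lineage a
sparse program (see below).

**Numerical choices.** Ratios for genes the cell does not detect count as
zero folds (excluding them would inflate the scale estimate); "nearest
integer" is resolved as *half away from zero* (`3.5 → 4`), a fixed, tested
policy; genes with `bg(g) = 0` are untouched. An optional prevalence filter
(`min_prevalence`, default 0 = off) restricts subtraction to genes detected
in a minimum fraction of empty barcodes, for users who want "batch genes"
read more narrowly. Whether cells should be QC-filtered before or after
correction is not dictated by the model; the package estimates the profile
from the unfiltered matrix and corrects the filtered one, and the acceptance
pipeline documents that order.

## Normalizations and pseudocells

`lognormalize` computes `log2(CPM/100 + 1)` (counts per 10,000), the
log-scale input for DEG calling, module scores and stage averages.
`total_normalize` scales each cell to 100,000 total counts, the linear-scale
input for group profiles and pseudocells. Pseudocells average every
`group_size = 50` same-cell-type cells *on the linear scale* — an average of
transcript fractions is again a transcript fraction, so pseudocell rows stay
on the 100,000 simplex; averaging log values would not commute with the
normalization. The remainder-group policy (keep trailing groups of at least
`min_size = 10`, drop smaller ones with a warning) is a package choice where
no convention exists; both knobs are exposed.

## TF specificity

For TF *g*, the cross-group mean profile is normalized to a probability
vector `p_g`, and

`score(g, l) = 1 − sqrt(JSD(p_g, e_l))`

with `e_l` the indicator distribution of group *l*. Two choices matter:

* **Reference distribution.** The score is computed against each group's
  indicator vector — the classic tissue-specificity construction that the
  `1 − sqrt(JSD)` form implies. A TF scores 1 in a group if and only if it
  is exclusively expressed there.
* **Logarithm base.** JSD uses base 2, which bounds the divergence by 1 and
  the score to `[0, 1]`; a natural-log JSD could exceed 1 and drive scores
  negative.

Z-scoring is **within TF, across groups** (sample sd; constant rows map to
zeros): the question answered is "which of the lineages is this TF specific
to", which requires comparing a TF against itself across lineages. The
alternative (within lineage, across TFs) would rank TFs against each other
instead; the raw scores are kept alongside the z-scores so either reading
can be reconstructed. Calls take the top `k = 20` per group, ties broken by
raw score then gene identifier, so rankings are deterministic.

Cross-species conservation intersects call sets through ortholog pair tables
(one2one and one2many relations both count): an anchor TF is conserved in a
lineage if every other species has at least one called ortholog in that
lineage. The TF universe itself is an external input — the package never
fetches databases.

## Driver TFs

For a cell type present at two stages, per-TF specificity vectors `Y1`, `Y2`
are computed within each stage across its cell types, and

`h_g = T(S(Y1))_g · T(S(Y2))_g`

where `S` standardizes to zero mean and unit variance (sample sd, n−1;
constant vectors map to zeros, and fewer than 3 shared TFs is an error) and
`T` zeroes negatives so TFs below average specificity at either stage drop
out. `h ≥ 0` always, and `h` is symmetric in the two stages and invariant to
positive affine rescaling of either input. The top `k = 5` TFs are reported;
zero-score TFs pad the list only when fewer than `k` are positive, and are
flagged. How cell types were matched across stages in the motivating
analyses (manifold-alignment edges) is not reproducible without those tools,
so the package matches **by identical annotation label**, with an explicit
`cell_type2` argument for user-supplied pairings.

## Trajectory modules

The procedure runs per cell population across ordered stages, with the
penultimate stage (NF59, the metamorphic climax) in the distinguished role:

1. **DEGs** between stages: detected in ≥ 10% of cells in at least one
   stage, |log fold change| ≥ 0.1 in the natural-log de-logged-mean
   convention `ln(mean(2^x − 1) + 1)`, two-sided Wilcoxon BH-adjusted
   p < 0.05.
2. **Stage averages**: per stage, means of de-logged values re-logged as
   `log2(mean + 1)`, then row-standardized; constant rows are excluded
   (they carry no trajectory).
3. **Fuzzy c-means** on the standardized profiles. The fuzzifier default is
   `m = 1.25` (soft but decisive memberships; `m → 1` approaches k-means),
   cluster counts of 15–30 suit atlas-scale gene sets while planted data
   use fewer. Centers initialize at seeded sampled profiles; a profile at
   exactly zero distance from a center takes full membership there (no
   division by zero); the objective `Σ u^m d²` is recorded every iteration
   and is non-increasing by construction — both facts are asserted in tests.
4. **Module scores**: per cluster, each cell's mean expression over the
   cluster's genes minus its mean over expression-bin-matched control genes
   (24 bins, 100 controls per gene, sampled with replacement only when a bin
   is small). The control pool is the *union* of sampled controls, which
   makes the degenerate case "controls = gene set" give exactly zero.
5. **Significance**: per cluster and stage, `n_tests = 1000` two-sided
   Wilcoxon rank-sum tests between subsamples of the first stage and the
   comparison stage, p-values averaged. The subsample size is
   `clamp(min stage size, 150, 1000)`; both sides are drawn without
   replacement (the procedure's description fixes only the 150–1000 range).
   BH correction runs over all (cluster, stage) pairs and a cluster
   proceeds if any `q < 1e-10`.
6. **Classification** by one-sided tests on the same resampling machinery at
   `direction_alpha = 0.05`: module 1 if climax scores exceed every other
   stage, module 2 if below every other stage, module 3/4 if successive
   stages are consistently down/up. Modules are tested in that order and
   the first pass wins; 1 and 2 are mutually exclusive by construction, and
   clusters passing nothing stay unassigned. Genes inherit their
   argmax-membership cluster's module — cluster-level calls are the
   statistical unit, the hard gene call is a reporting convention.

`shared_gene_frequency` then counts, per gene and module, how many cell
types' module sets contain the gene.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X ≥ k)` (`k = 0` gives p = 1) with BH correction across terms. The
annotation is a plain term → gene table and the universe is explicit —
ontology structure, term propagation and web services are out of scope.
Whether the conventional 0.05 gate applies to raw or adjusted values is
exposed (`on_adjusted`, default adjusted).

## The synthetic atlas: what it emulates, and what it does not

`generate_atlas` builds a stated world, not a tuned one:

* **Programs.** Each lineage expresses a sparse subset of genes
  (`gene_on_prob = 0.25` per lineage), with log-normal base abundances
  (sdlog 0.5) and negative binomial counts (dispersion 0.4, variance
  `mu + 0.4 mu²`). Sparsity is load-bearing: the median-fold estimator
  assumes most background genes are outside a given cell's program, as they
  are in real transcriptomes where each cell expresses a few thousand of
  tens of thousands of genes.
* **Depth.** `mean_umis_per_cell = 25000` over 1,000 genes puts the
  per-gene ambient intensity at roughly 1–3 UMIs per cell — the regime in
  which integer-rounded subtraction is resolvable gene by gene. Real
  barcodes carry fewer UMIs spread over many more genes; the generator
  compresses the gene axis, not the per-gene signal.
* **Ambient pool.** A library-size-weighted mixture of all programs
  (modelling lysis supernatant), mixed into every cell as a multinomial
  draw of `round(ambient_fraction × endogenous total)` UMIs — so the
  planted ambient share of the observed total is `af/(1 + af)`, about 9%
  at the default `ambient_fraction = 0.1`. Real ambient fractions are not
  quantified; 10% is chosen for testability. Empty barcodes are pure
  ambient draws with totals uniform on 50–400 UMIs, safely below the
  500-UMI cell threshold.
* **Planted TFs.** Endogenously exclusive to one lineage, at
  `tf_fold_change = 8` times their base abundance there; ambient mixing
  re-introduces them everywhere, which is exactly what the correction must
  remove. Non-planted TFs span two lineage programs: broad enough that no
  decoy is chance-exclusive (their specificity tops out near the
  two-lineage ceiling of ~0.44), narrow enough that they do not swamp the
  background-scale estimator the way a large ubiquitous class would at
  1,000-gene scale.
* **Trajectory archetypes.** Multiplicative log2-scale bumps of amplitude
  `module_effect_size = 1`: a climax peak (with 0.3-amplitude shoulders),
  its mirror trough, and strictly monotone down/up ramps. Expected totals
  are renormalized per stage so archetypes change composition, not depth.
  Module genes follow the sparse programs like any other gene (each
  expressed in at least one lineage); a ubiquitously responding population
  is obtained with `gene_on_prob = 1`, as the module-recovery tests do.
* **Not emulated.** Doublets, batch effects beyond a single shared ambient
  pool per batch, UMI sequencing errors, cell-type hierarchies within
  lineages, stage-varying ambient composition. A green recovery test
  therefore establishes that the estimators invert the generative model
  they assume — not that they are robust to artifacts the generator does
  not produce.

## Determinism

Every randomized operation takes an explicit integer seed and runs under a
temporary RNG state (`with_seed`), so calls never perturb each other or the
session; derived seeds keep sub-operations (per-cluster resampling, control
sampling) independent but reproducible. The full pipeline is bit-identical
under a fixed seed, which the acceptance suite asserts.

## Known limitations

* The background scale is a single per-cell scalar; composition differences
  between a cell's ambient exposure and the batch pool are not modelled.
* Label-based cell-type matching for driver TFs inherits any annotation
  drift between stages.
* The Wilcoxon implementation is the large-sample normal approximation with
  tie and continuity corrections (validated against the reference
  implementation); exact small-sample p-values are not used, which is
  immaterial at the ≥ 150-cell subsample sizes the resampling procedure
  mandates.
* Averaged p-values from overlapping subsamples are correlated when a stage
  has barely more cells than the subsample size; the `q < 1e-10` gate is
  conservative enough that this does not create false module calls in the
  recovery tests.
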