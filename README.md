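# scMetamorph

Post-quantification analysis for droplet single-cell atlases that span
amphibian metamorphosis — the thyroid-hormone-driven remodeling that carries
a *Xenopus* tadpole from premetamorphosis (NF48) through the metamorphic
climax (NF59) to the end of metamorphosis (NF66) and adulthood. The package
is aimed at analysts who already have UMI count matrices (Matrix Market
triplet or dense CSV) plus per-barcode annotations (batch, stage, tissue,
cell type, lineage) and need the bespoke statistics that sit between
quantification and interpretation:

1. **Ambient RNA (batch gene background) correction.** Barcodes with fewer
   than 500 UMIs are treated as empty beads exposed to cell-free RNA. Per
   batch, the background of gene *g* is its mean count over those barcodes,
   `bg(g)`. For each cell *c* the background is rescaled by the median fold
   difference `s(c) = median_{g : bg(g) > 0} count(c,g) / bg(g)`, rounded to
   the nearest integer, and subtracted with clipping:
   `corrected(c,g) = max(0, count(c,g) − round(bg(g) · s(c)))`.
2. **Normalizations and pseudocells.** `log2(CPM/100 + 1)` for log-scale
   analyses; counts scaled to 100,000 per cell for linear-scale work;
   seeded aggregation of every 50 same-cell-type cells into pseudocells for
   cross-species comparison prep.
3. **TF specificity via Jensen–Shannon divergence.** For TF *g* with
   cross-group probability profile `p_g`, the specificity for group *l* is
   `score(g,l) = 1 − sqrt(JSD(p_g, e_l))` with base-2 JSD and `e_l` the
   group's indicator distribution, so scores live in [0, 1] and reach 1 only
   for a perfectly group-exclusive TF. Z-scored scores rank the specific TFs
   per lineage; ortholog maps intersect calls across species.
4. **Driver TFs across stages.** For a cell type matched between two stages
   with per-TF specificity vectors `Y1`, `Y2`:
   `h_g = T(S(Y1))_g · T(S(Y2))_g`, where `S` standardizes and `T` truncates
   negatives to zero; the top 5 TFs by `h` are the drive TFs.
5. **Trajectory modules.** Stage DEGs → stage-averaged, standardized gene
   profiles → fuzzy c-means → per-cell module scores against
   expression-matched controls → 1000 (configurable) subsampled Wilcoxon
   rank-sum tests per stage with averaged p-values → BH correction with a
   `q < 1e-10` gate → one-sided tests classify each cluster as module 1
   (climax peak), 2 (climax trough), 3 (monotone down) or 4 (monotone up) →
   cross-cell-type shared-gene frequencies.
6. **Enrichment.** One-sided hypergeometric over-representation with
   Benjamini–Hochberg correction.

A synthetic atlas generator (`generate_atlas`) plants all of this structure
— a shared ambient profile, sub-500-UMI empty barcodes, single-lineage TFs,
four trajectory archetypes — and returns the ground truth, so every stage of
the pipeline is verified by parameter recovery without downloading anything.

## Worked example

```r
library(scMetamorph)

atlas <- generate_atlas(atlas_config(n_empty_barcodes = 5000, seed = 1))
profile   <- estimate_background_profile(atlas$counts)   # from the unfiltered matrix
corrected <- correct_background(filter_cells(atlas$counts), profile)
profile
#> BackgroundProfile: batch batch1, 5000 background barcodes (< 500 UMIs), 848/1000 genes with background > 0

em    <- lognormalize(corrected)
prof  <- group_mean_profile(em, group_key = "lineage")
tfs   <- grep("^TF", rownames(prof), value = TRUE)
st    <- specificity_scores(prof, tfs = tfs)
calls <- call_specific_tfs(zscore_scores(st), k = 5)
head(calls$epidermis, 5)
#>    gene   zscore       raw
#> 1 TF004 1.788854 0.9897263
#> 2 TF002 1.788854 0.9797970
#> 3 TF001 1.788854 0.9673519
#> 4 TF003 1.788853 0.9687423
#> 5 TF027 1.200556 0.4657002
```

The four planted epidermis TFs (`TF001`–`TF004`) head their lineage's
ranking with raw scores near 1 (group-exclusive expression survives the
ambient correction); the first non-planted TF follows near the two-lineage
ceiling of ~0.44. The `zscore` column is the across-lineage standardized
score used for the ranking; `raw` is `1 − sqrt(JSD)` itself.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on seeded synthetic data —
atlas generation, background correction, lineage TF calls, driver TFs
between NF48 and NF54, trajectory-module classification at
`n_tests = 200`, and an enrichment of a recovered module against the
planted archetype sets — and writes the results JSON to `--out`.
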