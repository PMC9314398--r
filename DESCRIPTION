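Package: scMetamorph
Title: Ambient Correction, TF Specificity and Trajectory Modules for
    Developmental Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-quantification analysis of droplet single-cell atlases
    spanning amphibian metamorphosis. Implements batch-wise ambient RNA
    background estimation from sub-threshold (empty bead) barcodes and
    median-fold-scaled integer subtraction; CPM-based normalizations and
    pseudocell aggregation for cross-species comparison; Jensen-Shannon
    divergence transcription factor specificity scores with z-score calls
    and cross-species conservation; cross-stage driver-TF scoring; a fuzzy
    c-means trajectory-module procedure with resampled Wilcoxon stage tests
    and four-module classification; one-sided hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction; and a synthetic atlas
    generator with planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
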