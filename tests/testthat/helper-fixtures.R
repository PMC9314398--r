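# Shared in-code fixtures: all synthetic, built at test time.

# tiny deterministic CountMatrix with metadata
toy_counts <- function() {
  v <- matrix(c(4L, 0L, 2L,
                0L, 3L, 1L,
                5L, 5L, 0L,
                1L, 0L, 0L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("bc", 1:4), paste0("g", 1:3)))
  meta <- data.frame(barcode = paste0("bc", 1:4),
                     batch = "b1",
                     stage = c("NF48", "NF48", "NF54", "NF54"),
                     cell_type = c("t1", "t2", "t1", "t2"),
                     lineage = c("l1", "l2", "l1", "l2"),
                     stringsAsFactors = FALSE)
  CountMatrix(v, meta = meta)
}

# small atlas config used across unit tests (fast to generate);
# ... overrides any default
small_cfg <- function(seed = 1, ...) {
  args <- list(n_genes = 200, n_tfs = 20,
               lineages = c(epidermis = 60, immune = 60, neural = 60, muscle = 60),
               planted_tfs_per_lineage = 2,
               module_genes_per_archetype = 10,
               n_empty_barcodes = 200,
               mean_umis_per_cell = 4000,
               seed = seed)
  do.call(atlas_config, utils::modifyList(args, list(...)))
}

# the TF-recovery world: 5 lineages x 20 planted TFs, fold 8, 500 cells each
tf_cfg <- function(seed) {
  atlas_config(n_genes = 1000, n_tfs = 150,
               lineages = c(epidermis = 500, immune = 500, neural = 500,
                            muscle = 500, endoderm = 500),
               planted_tfs_per_lineage = 20, tf_fold_change = 8,
               module_genes_per_archetype = 0,
               n_empty_barcodes = 1000,
               seed = seed)
}

# the module-recovery world: one cell population, 4 stages x 500 cells,
# 4 archetypes x 50 genes + 200 null genes, all genes in the program
module_cfg <- function(seed) {
  atlas_config(n_genes = 400, n_tfs = 0,
               lineages = c(enterocyte = 2000),
               planted_tfs_per_lineage = 0,
               module_genes_per_archetype = 50, module_effect_size = 1,
               gene_on_prob = 1,
               n_empty_barcodes = 0,
               mean_umis_per_cell = 8000,
               seed = seed)
}

# correct an atlas end to end: filter, estimate background, subtract
corrected_cells <- function(atlas, min_transcripts = 500) {
  prof <- estimate_background_profile(atlas$counts, umi_threshold = 500)
  cells <- filter_cells(atlas$counts, min_transcripts = min_transcripts)
  correct_background(cells, prof)
}
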