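#' Configuration for the synthetic atlas generator
#'
#' Describes a droplet-style atlas of several cell lineages sampled across
#' ordered developmental stages, with a shared ambient (cell-free RNA)
#' profile mixed into every barcode and a population of sub-threshold empty
#' barcodes. Ground-truth structure is planted for recovery testing:
#' single-lineage transcription factors and stage-trajectory genes following
#' four module archetypes (1: peak at the metamorphic climax, 2: trough
#' there, 3: monotone decreasing, 4: monotone increasing).
#'
#' Default scales are chosen for testability at desk size, not fidelity to
#' any real atlas: ~25,000 UMIs over 1,000 genes puts the per-gene ambient
#' intensity at roughly 1--3 UMIs per cell, the regime in which integer
#' background subtraction is resolvable gene by gene.
#'
#' @param n_genes total genes (TFs included).
#' @param n_tfs number of genes designated transcription factors (the first
#'   `n_tfs` genes, named `TF...`).
#' @param lineages named integer vector: cells per lineage (split evenly
#'   across stages).
#' @param stages ordered stage labels; the penultimate stage plays the
#'   metamorphic climax (NF59) role. At least 3 stages.
#' @param include_adult append an `"adult"` stage reusing each archetype's
#'   final-stage level (default off).
#' @param ambient_fraction expected ambient UMIs as a fraction of each
#'   cell's endogenous total, in \[0, 1).
#' @param n_empty_barcodes number of pure-ambient empty barcodes.
#' @param empty_umi_range integer (low, high): empty-barcode totals are
#'   uniform on this range; keep `high` below the 500-UMI cell threshold.
#' @param nb_dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2), shared across genes.
#' @param mean_umis_per_cell expected endogenous UMI total per cell.
#' @param planted_tfs_per_lineage single-lineage TFs planted per lineage
#'   (disjoint across lineages); remaining TFs are expressed in all
#'   lineages (housekeeping regulators) so specificity ground truth is
#'   unambiguous.
#' @param tf_fold_change expression multiplier of a planted TF in its own
#'   lineage (> 1); planted TFs are endogenously silent elsewhere.
#' @param module_genes_per_archetype trajectory genes planted per archetype,
#'   expressed in all lineages.
#' @param module_effect_size log2-scale amplitude of the archetype bump.
#' @param gene_on_prob probability an ordinary gene is part of a given
#'   lineage's program (sparse, partially overlapping programs).
#' @param batch batch label recorded in the metadata.
#' @param seed generator seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `AtlasConfig`.
#' @export
atlas_config <- function(n_genes = 1000, n_tfs = 100,
                         lineages = c(epidermis = 400, immune = 400, neural = 400,
                                      muscle = 400, endoderm = 400),
                         stages = c("NF48", "NF54", "NF59", "NF66"),
                         include_adult = FALSE,
                         ambient_fraction = 0.1,
                         n_empty_barcodes = 2000,
                         empty_umi_range = c(50, 400),
                         nb_dispersion = 0.4,
                         mean_umis_per_cell = 25000,
                         planted_tfs_per_lineage = 4,
                         tf_fold_change = 8,
                         module_genes_per_archetype = 50,
                         module_effect_size = 1,
                         gene_on_prob = 0.25,
                         batch = "batch1",
                         seed = 1) {
  cfg <- as.list(environment())
  if (is.null(names(lineages)) || any(names(lineages) == ""))
    stop("lineages must be a named vector of cell counts")
  if (length(stages) < 3) stop("at least 3 stages are required for module archetypes")
  if (ambient_fraction < 0 || ambient_fraction >= 1)
    stop("ambient_fraction must be in [0, 1)")
  if (planted_tfs_per_lineage * length(lineages) > n_tfs)
    stop("planted TF demand exceeds n_tfs")
  if (n_tfs + 4 * module_genes_per_archetype > n_genes)
    stop("planted gene demand (TFs + module genes) exceeds n_genes")
  if (length(empty_umi_range) != 2 || empty_umi_range[1] > empty_umi_range[2])
    stop("empty_umi_range must be (low, high) with low <= high")
  if (empty_umi_range[2] >= mean_umis_per_cell)
    stop("empty_umi_range high must be below the cell UMI scale")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (tf_fold_change <= 1) stop("tf_fold_change must be > 1")
  structure(cfg, class = "AtlasConfig")
}

# archetype shapes over S stages (climax = penultimate):
# 1 climax peak, 2 climax trough, 3 monotone down, 4 monotone up
archetype_shapes <- function(S) {
  climax <- S - 1
  peak <- numeric(S)
  peak[climax] <- 1
  if (climax > 1) peak[climax - 1] <- 0.3
  if (climax < S) peak[climax + 1] <- 0.3
  down <- seq(1, 0, length.out = S)
  rbind(peak, -peak, down, rev(down))
}

#' Generate a synthetic atlas with planted ground truth
#'
#' Each cell's observed counts are an endogenous negative binomial draw from
#' its lineage-by-stage program plus a multinomial ambient draw of
#' `round(ambient_fraction x endogenous total)` UMIs from the shared ambient
#' profile (a library-size-weighted mixture of all programs, modelling lysis
#' supernatant). Empty barcodes are pure ambient draws with sub-threshold
#' totals. Observed = endogenous + ambient exactly, per barcode per gene.
#'
#' @param cfg an [atlas_config()].
#' @return A list with `counts` (the observed [CountMatrix()], cells then
#'   empty barcodes, metadata filled for cells) and `truth`, a `GroundTruth`
#'   list holding `endogenous_counts` (cells only), `ambient_profile`,
#'   `per_cell_ambient_count` (ambient UMIs per barcode, empties included),
#'   `planted_tf_sets`, `module_archetype` (0 = none), `empty_barcodes`, and
#'   `expected_means` (per lineage, the gene x stage expected endogenous
#'   mean matrix).
#' @export
generate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "AtlasConfig"))
  with_seed(cfg$seed, generate_atlas_impl(cfg))
}

generate_atlas_impl <- function(cfg) {
  L <- names(cfg$lineages)
  stages <- cfg$stages
  if (cfg$include_adult) stages <- c(stages, "adult")
  S <- length(stages)
  nG <- cfg$n_genes
  genes <- c(sprintf("TF%03d", seq_len(cfg$n_tfs)),
             sprintf("g%04d", seq_len(nG - cfg$n_tfs) + cfg$n_tfs))

  base <- stats::rlnorm(nG, meanlog = 0, sdlog = 0.5)

  # lineage membership: ordinary genes sparse; non-planted TFs span two
  # lineage programs (broad, but never chance-exclusive, so planted TFs are
  # the only single-lineage regulators); planted TFs exclusive to theirs
  on <- matrix(stats::rbinom(nG * length(L), 1, cfg$gene_on_prob),
               nG, length(L), dimnames = list(genes, L))
  if (cfg$n_tfs > 0) {
    for (i in seq_len(cfg$n_tfs)) {
      on[i, ] <- 0
      on[i, sample(length(L), min(2, length(L)))] <- 1
    }
  }

  planted <- list()
  fold <- matrix(1, nG, length(L), dimnames = list(genes, L))
  if (cfg$planted_tfs_per_lineage > 0) {
    for (i in seq_along(L)) {
      idx <- (i - 1) * cfg$planted_tfs_per_lineage + seq_len(cfg$planted_tfs_per_lineage)
      planted[[L[i]]] <- genes[idx]
      on[idx, ] <- 0
      on[idx, i] <- 1
      fold[idx, i] <- cfg$tf_fold_change
    }
  }

  module_archetype <- stats::setNames(integer(nG), genes)
  shapes <- archetype_shapes(length(cfg$stages))
  if (cfg$include_adult) shapes <- cbind(shapes, shapes[, ncol(shapes)])
  stage_factor <- matrix(1, nG, S, dimnames = list(genes, stages))
  if (cfg$module_genes_per_archetype > 0) {
    for (a in 1:4) {
      idx <- cfg$n_tfs + (a - 1) * cfg$module_genes_per_archetype +
        seq_len(cfg$module_genes_per_archetype)
      module_archetype[idx] <- a
      # module genes follow the sparse lineage programs like any other gene
      # (set gene_on_prob = 1 for a ubiquitously responding population), but
      # each is expressed in at least one lineage so the planting is real
      silent <- idx[rowSums(on[idx, , drop = FALSE]) == 0]
      if (length(silent))
        on[cbind(silent, sample(length(L), length(silent), replace = TRUE))] <- 1
      stage_factor[idx, ] <- rep(2^(cfg$module_effect_size * shapes[a, ]),
                                 each = length(idx))
    }
  }

  B <- base * on * fold                     # genes x lineages
  n_per <- lapply(cfg$lineages, function(n) diff(round(seq(0, n, length.out = S + 1))))

  expected_means <- list()
  mu_ls <- list()
  for (l in L) {
    E <- B[, l] * stage_factor              # genes x stages
    E <- sweep(E, 2, colSums(E), "/") * cfg$mean_umis_per_cell
    expected_means[[l]] <- E
    mu_ls[[l]] <- E
  }

  # ambient profile: library-size-weighted mixture of all programs
  w <- Reduce(`+`, lapply(L, function(l)
    mu_ls[[l]] %*% matrix(n_per[[l]], ncol = 1)))
  ambient_profile <- as.vector(w) / sum(w)
  names(ambient_profile) <- genes

  endo_rows <- list(); meta_rows <- list()
  for (l in L) {
    for (s in seq_len(S)) {
      nc <- n_per[[l]][s]
      if (nc == 0) next
      mu <- mu_ls[[l]][, s]
      m <- matrix(stats::rnbinom(nc * nG, mu = rep(mu, each = nc),
                                 size = 1 / cfg$nb_dispersion), nc, nG)
      rownames(m) <- sprintf("cell_%s_%s_%04d", l, stages[s], seq_len(nc))
      endo_rows[[paste(l, s)]] <- m
      meta_rows[[paste(l, s)]] <- data.frame(
        barcode = rownames(m), batch = cfg$batch, stage = stages[s],
        tissue = l, cell_type = l, lineage = l, stringsAsFactors = FALSE)
    }
  }
  endo <- do.call(rbind, endo_rows)
  colnames(endo) <- genes
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL

  amb_n <- as.integer(round(cfg$ambient_fraction * rowSums(endo)))
  amb <- matrix(0L, nrow(endo), nG)
  nz <- which(amb_n > 0)
  if (length(nz)) {
    draws <- vapply(amb_n[nz], function(n)
      stats::rmultinom(1, n, ambient_profile)[, 1], integer(nG))
    amb[nz, ] <- t(draws)
  }
  observed <- endo + amb

  empty <- NULL; empty_bc <- character(0); empty_tot <- integer(0)
  if (cfg$n_empty_barcodes > 0) {
    empty_tot <- sample(seq(cfg$empty_umi_range[1], cfg$empty_umi_range[2]),
                        cfg$n_empty_barcodes, replace = TRUE)
    empty <- t(vapply(empty_tot, function(n)
      stats::rmultinom(1, n, ambient_profile)[, 1], integer(nG)))
    empty_bc <- sprintf("empty_%05d", seq_len(cfg$n_empty_barcodes))
    rownames(empty) <- empty_bc
    colnames(empty) <- genes
    meta <- rbind(meta, data.frame(barcode = empty_bc, batch = cfg$batch,
                                   stage = NA_character_, tissue = NA_character_,
                                   cell_type = NA_character_, lineage = NA_character_,
                                   stringsAsFactors = FALSE))
  }

  values <- rbind(observed, empty)
  storage.mode(values) <- "integer"
  counts <- CountMatrix(values, meta = meta)

  storage.mode(endo) <- "integer"
  truth <- structure(list(
    endogenous_counts = CountMatrix(endo, meta = meta[match(rownames(endo), meta$barcode), ]),
    ambient_profile = ambient_profile,
    per_cell_ambient_count = stats::setNames(c(amb_n, empty_tot),
                                             c(rownames(endo), empty_bc)),
    planted_tf_sets = planted,
    module_archetype = module_archetype,
    empty_barcodes = empty_bc,
    expected_means = expected_means,
    stages = stages,
    config = cfg), class = "GroundTruth")

  list(counts = counts, truth = truth)
}

#' Write a generated atlas to disk
#'
#' Writes the Matrix Market triplet, the metadata TSV, and the ground truth
#' (planted sets and per-barcode ambient totals) as JSON.
#'
#' @param atlas result of [generate_atlas()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  write_counts(atlas$counts, dir)
  write_table(atlas$counts$meta, file.path(dir, "metadata.tsv"), "tsv")
  tr <- atlas$truth
  jsonlite::write_json(list(
    ambient_profile = tr$ambient_profile,
    per_cell_ambient_count = as.list(tr$per_cell_ambient_count),
    planted_tf_sets = tr$planted_tf_sets,
    module_archetype = as.list(tr$module_archetype[tr$module_archetype > 0]),
    empty_barcodes = tr$empty_barcodes),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
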