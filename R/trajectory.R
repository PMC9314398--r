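# Wilcoxon rank-sum p via the normal approximation with tie and continuity
# corrections (the same approximation stats::wilcox.test uses for large
# samples). Hand-rolled for speed: the resampling procedure calls this tens
# of thousands of times.
wilcox_p <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  nties <- table(r)
  sigma <- sqrt((nx * ny / 12) *
                  ((nx + ny + 1) - sum(nties^3 - nties) / ((nx + ny) * (nx + ny - 1))))
  if (sigma == 0) return(1)
  z <- W - mu
  p <- switch(alternative,
    two.sided = {
      zz <- (z - sign(z) * 0.5) / sigma
      2 * min(stats::pnorm(zz), stats::pnorm(zz, lower.tail = FALSE))
    },
    greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((z + 0.5) / sigma))
  min(p, 1)
}

#' Differentially expressed genes between two stages
#'
#' A gene is kept when it is detected in at least `min_pct` of cells in at
#' least one stage, its log fold change passes `logfc_threshold`, and its
#' two-sided Wilcoxon rank-sum p-value survives Benjamini-Hochberg
#' correction at `alpha`. The fold change follows the natural-log
#' de-logged-mean convention on log2cp10k input:
#' `ln(mean(2^x - 1) + 1)` difference between stages.
#'
#' @param em an [ExpressionMatrix()] on the log2cp10k scale.
#' @param meta per-barcode metadata with `stage` (defaults to the matrix's
#'   own).
#' @param stage_a,stage_b the two stages to compare (each needs >= 3 cells).
#' @param logfc_threshold minimum |log fold change| (default 0.1).
#' @param min_pct minimum detection fraction in at least one stage
#'   (default 0.1).
#' @param alpha BH-adjusted p-value cutoff (default 0.05).
#' @return Character vector of DEG identifiers, with the per-gene statistics
#'   table attached as attribute `"stats"`.
#' @export
find_stage_degs <- function(em, meta = NULL, stage_a, stage_b,
                            logfc_threshold = 0.1, min_pct = 0.1, alpha = 0.05) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  meta <- meta %||% em$meta
  st <- meta$stage[match(rownames(em$values), meta$barcode)]
  ia <- which(!is.na(st) & st == stage_a)
  ib <- which(!is.na(st) & st == stage_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop("each stage needs at least 3 cells (", stage_a, ": ", length(ia),
         ", ", stage_b, ": ", length(ib), ")")
  va <- em$values[ia, , drop = FALSE]
  vb <- em$values[ib, , drop = FALSE]
  pct_a <- colMeans(va > 0)
  pct_b <- colMeans(vb > 0)
  lin_a <- if (em$normalization == "log2cp10k") 2^va - 1 else va
  lin_b <- if (em$normalization == "log2cp10k") 2^vb - 1 else vb
  logfc <- log(colMeans(lin_a) + 1) - log(colMeans(lin_b) + 1)
  pass <- (pct_a >= min_pct | pct_b >= min_pct) & abs(logfc) >= logfc_threshold
  genes <- colnames(em$values)
  p <- rep(NA_real_, length(genes))
  for (g in which(pass)) p[g] <- wilcox_p(va[, g], vb[, g], "two.sided")
  padj <- rep(NA_real_, length(genes))
  if (any(pass)) padj[pass] <- bh_adjust(pmax(p[pass], .Machine$double.xmin))
  keep <- pass & !is.na(padj) & padj < alpha
  stats_df <- data.frame(gene = genes, pct_a = pct_a, pct_b = pct_b,
                         logfc = logfc, p = p, padj = padj, deg = keep,
                         stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  structure(genes[keep], stats = stats_df)
}

#' Stage-averaged expression profiles
#'
#' Per stage, the arithmetic mean of de-logged values (`2^x - 1`) is taken
#' and re-logged as `log2(mean + 1)`; each gene's profile is then
#' standardized to zero mean and unit variance across stages (sample sd), the
#' form the fuzzy clustering expects. Constant genes cannot be standardized:
#' they are excluded and listed in attribute `"excluded"`.
#'
#' @param em an [ExpressionMatrix()] (log2cp10k).
#' @param meta metadata with `stage` (defaults to the matrix's own).
#' @param stages ordered stage labels; every stage must have cells.
#' @param standardize row-standardize (default TRUE).
#' @return gene x stage matrix; the unstandardized averages are attached as
#'   attribute `"raw"`.
#' @export
stage_average <- function(em, meta = NULL, stages, standardize = TRUE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  meta <- meta %||% em$meta
  st <- meta$stage[match(rownames(em$values), meta$barcode)]
  lin <- linear_values(em)
  avg <- vapply(stages, function(s) {
    idx <- which(!is.na(st) & st == s)
    if (!length(idx)) stop("stage '", s, "' has no cells")
    log2(colMeans(lin[idx, , drop = FALSE]) + 1)
  }, numeric(ncol(lin)))
  rownames(avg) <- colnames(em$values)
  if (!standardize) return(avg)
  sds <- apply(avg, 1, stats::sd)
  excluded <- rownames(avg)[!is.finite(sds) | sds == 0]
  if (length(excluded))
    log_msg(length(excluded), " constant gene profile(s) excluded from standardization")
  keep <- setdiff(rownames(avg), excluded)
  out <- t(scale(t(avg[keep, , drop = FALSE])))
  dimnames(out) <- list(keep, stages)
  structure(out, raw = avg, excluded = excluded)
}

#' Fuzzy c-means clustering of gene profiles
#'
#' Standard fuzzy c-means with Euclidean distance: memberships
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2 / (m - 1))`, centers the
#' `u^m`-weighted means, iterated until the largest center shift falls below
#' `tol`. A profile at exactly zero distance from a center receives full
#' membership in (the nearest of) such cluster(s). The objective
#' `sum u^m d^2` is recorded each iteration and is non-increasing.
#'
#' @param X gene x stage matrix (rows standardized; see [stage_average()]).
#' @param c number of clusters (2 <= c < number of genes).
#' @param m fuzzifier (> 1, default 1.25; values near 1 approach hard
#'   k-means).
#' @param tol convergence tolerance on the center shift (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param seed seed for the initial centers (sampled rows of `X`).
#' @return A `FuzzyClustering` list: `centers` (cluster x stage),
#'   `membership` (gene x cluster, rows summing to 1), `fuzzifier`,
#'   `n_iter`, `objective` and the per-iteration `objective_trace`.
#' @export
fuzzy_cmeans <- function(X, c, m = 1.25, tol = 1e-6, max_iter = 300, seed = 1) {
  stopifnot(is.matrix(X))
  if (any(!is.finite(X))) stop("non-finite values in the clustering input")
  if (c < 2 || c >= nrow(X)) stop("need 2 <= c < number of genes")
  if (m <= 1) stop("fuzzifier m must be > 1")
  centers <- X[with_seed(seed, sample(nrow(X), c)), , drop = FALSE]
  rownames(centers) <- paste0("cluster_", seq_len(c))
  expo <- 1 / (m - 1)
  trace <- numeric(0)
  U <- NULL
  membership_of <- function(d2) {
    U <- matrix(0, nrow(d2), ncol(d2), dimnames = dimnames(d2))
    zero <- d2 <= .Machine$double.eps
    hasz <- rowSums(zero) > 0
    if (any(hasz))
      U[hasz, ] <- t(apply(zero[hasz, , drop = FALSE], 1, function(z) {
        u <- numeric(length(z)); u[which(z)[1]] <- 1; u
      }))
    if (any(!hasz)) {
      inv <- (1 / d2[!hasz, , drop = FALSE])^expo
      U[!hasz, ] <- inv / rowSums(inv)
    }
    U
  }
  dist2_to <- function(centers) {
    d2 <- vapply(seq_len(nrow(centers)), function(k)
      rowSums(sweep(X, 2, centers[k, ])^2), numeric(nrow(X)))
    dimnames(d2) <- list(rownames(X), rownames(centers))
    d2
  }
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to(centers)
    U <- membership_of(d2)
    trace <- c(trace, sum(U^m * d2))
    Um <- U^m
    newc <- (t(Um) %*% X) / colSums(Um)
    rownames(newc) <- rownames(centers)
    shift <- max(abs(newc - centers))
    centers <- newc
    if (shift < tol) break
  }
  d2 <- dist2_to(centers)
  U <- membership_of(d2)
  trace <- c(trace, sum(U^m * d2))
  structure(list(centers = centers, membership = U, fuzzifier = m,
                 n_iter = it, objective = trace[length(trace)],
                 objective_trace = trace),
            class = "FuzzyClustering")
}

#' @export
print.FuzzyClustering <- function(x, ...) {
  cat(sprintf("FuzzyClustering: %d genes x %d clusters (m = %g, %d iterations, objective %.4g)\n",
              nrow(x$membership), ncol(x$membership), x$fuzzifier, x$n_iter,
              x$objective))
  invisible(x)
}

# hard gene -> cluster call by argmax membership (first on exact ties)
hard_clusters <- function(fc) {
  cl <- colnames(fc$membership)[max.col(fc$membership, ties.method = "first")]
  stats::setNames(cl, rownames(fc$membership))
}

#' Per-cell score of a gene set against expression-matched controls
#'
#' Genes are binned into `n_bins` by their average expression over all
#' cells; for each set gene `n_ctrl` control genes are sampled from its bin
#' (with replacement when the bin is smaller than `n_ctrl`). The score of a
#' cell is its mean expression over the set minus its mean over the pooled
#' (unique) control genes, so a shared additive shift cancels.
#'
#' @param em an [ExpressionMatrix()].
#' @param gene_set non-empty subset of the matrix's genes.
#' @param n_bins expression bins (default 24, capped at the gene count).
#' @param n_ctrl controls sampled per set gene (default 100).
#' @param seed sampling seed.
#' @return Named per-cell score vector; the control set is attached as
#'   attribute `"controls"`.
#' @export
module_score <- function(em, gene_set, n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (length(gene_set) == 0) stop("empty gene set")
  missing <- setdiff(gene_set, colnames(em$values))
  if (length(missing))
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  v <- em$values
  avg <- colMeans(v)
  n_bins <- min(n_bins, ncol(v))
  bins <- if (n_bins < 2) rep(1L, ncol(v)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- colnames(v)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- names(bins)[bins == bins[g]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })
  ctrl <- unique(ctrl)
  score <- rowMeans(v[, gene_set, drop = FALSE]) - rowMeans(v[, ctrl, drop = FALSE])
  structure(score, controls = ctrl)
}

# averaged p over n_tests subsampled Wilcoxon tests between two stages'
# score distributions; both sides drawn without replacement
resampled_wilcox <- function(scores, st, stage_x, stage_y, alternative,
                             n_tests, n_low, n_high, seed) {
  ix <- which(!is.na(st) & st == stage_x)
  iy <- which(!is.na(st) & st == stage_y)
  if (length(ix) < 3 || length(iy) < 3)
    stop("stage with fewer than 3 cells (", stage_x, ": ", length(ix), ", ",
         stage_y, ": ", length(iy), ")")
  n <- min(n_high, max(n_low, min(length(ix), length(iy))))
  if (n > min(length(ix), length(iy))) {
    n <- min(length(ix), length(iy))
    warning("fewer than ", n_low, " cells available; using n = ", n)
  }
  with_seed(seed, {
    mean(vapply(seq_len(n_tests), function(i) {
      wilcox_p(scores[sample(ix, n)], scores[sample(iy, n)], alternative)
    }, numeric(1)))
  })
}

#' Resampled Wilcoxon test of module scores against a reference stage
#'
#' For each non-reference stage, `n_tests` two-sided Wilcoxon rank-sum tests
#' are run between equally sized subsamples (without replacement) of the
#' reference and comparison stages --- `n` cells, clamped to
#' \[`n_low`, `n_high`\] and to the available stage sizes --- and the
#' p-values are averaged.
#'
#' @param scores per-cell score vector (see [module_score()]), named by
#'   barcode or aligned with `meta`.
#' @param meta per-barcode metadata with `stage`.
#' @param ref_stage reference (first) stage.
#' @param stages stages to compare (default: all other stages present).
#' @param n_tests tests to average (default 1000).
#' @param n_low,n_high clamp on the subsample size (defaults 150, 1000).
#' @param seed resampling seed.
#' @param alternative test sidedness (default two-sided).
#' @return Named vector of averaged p-values, one per comparison stage.
#' @export
resampling_stage_test <- function(scores, meta, ref_stage, stages = NULL,
                                  n_tests = 1000, n_low = 150, n_high = 1000,
                                  seed = 1, alternative = "two.sided") {
  st <- meta$stage[match(names(scores) %||% meta$barcode, meta$barcode)]
  if (is.null(names(scores))) st <- meta$stage
  stages <- stages %||% setdiff(unique(st[!is.na(st)]), ref_stage)
  stages <- setdiff(stages, ref_stage)
  seeds <- derive_seeds(seed, length(stages))
  out <- vapply(seq_along(stages), function(i) {
    resampled_wilcox(scores, st, ref_stage, stages[i], alternative,
                     n_tests, n_low, n_high, seeds[i])
  }, numeric(1))
  stats::setNames(out, stages)
}

#' Classify clusters into the four metamorphosis modules
#'
#' Benjamini-Hochberg correction is applied over all (cluster, stage)
#' averaged p-values from the reference-stage resampling test; clusters with
#' any `q < q_threshold` vary significantly and proceed to one-sided
#' resampled Wilcoxon tests on their scores. Module 1: climax-stage scores
#' exceed every other stage; module 2: climax scores are below every other
#' stage; module 3: each successive stage below the previous; module 4: each
#' successive stage above the previous. Modules are tested in that order and
#' the first to pass is assigned (1 and 2 are mutually exclusive by
#' construction); clusters passing none, or not significant, are
#' `"unassigned"`. Genes inherit the module of their argmax-membership
#' cluster.
#'
#' @param fc a [fuzzy_cmeans()] result.
#' @param scores_by_cluster named list: cluster -> per-cell score vector
#'   (from [module_score()] on that cluster's genes).
#' @param meta per-barcode metadata with `stage`.
#' @param stages ordered stage labels (first = reference).
#' @param climax_stage stage with the climax role (default: penultimate).
#' @param q_threshold significance gate on BH-adjusted averaged p
#'   (default 1e-10).
#' @param direction_alpha level for the one-sided averaged tests
#'   (default 0.05).
#' @param n_tests,n_low,n_high,seed resampling controls, as in
#'   [resampling_stage_test()].
#' @return A `ModuleAssignment` list: `cluster_module` (named,
#'   `"1"`..`"4"`/`"unassigned"`), `gene_module`, `stage_p` and `stage_q`
#'   (cluster x stage), and `significant`.
#' @export
classify_modules <- function(fc, scores_by_cluster, meta, stages,
                             climax_stage = NULL, q_threshold = 1e-10,
                             direction_alpha = 0.05, n_tests = 1000,
                             n_low = 150, n_high = 1000, seed = 1) {
  stopifnot(inherits(fc, "FuzzyClustering"))
  clusters <- colnames(fc$membership)
  stopifnot(all(clusters %in% names(scores_by_cluster)))
  climax_stage <- climax_stage %||% stages[length(stages) - 1]
  if (!climax_stage %in% stages) stop("climax stage '", climax_stage, "' not in stages")
  st_all <- meta$stage
  if (!climax_stage %in% st_all[!is.na(st_all)])
    stop("climax stage '", climax_stage, "' has no cells")
  comp_stages <- stages[-1]
  seeds <- derive_seeds(seed, length(clusters))

  stage_p <- t(vapply(seq_along(clusters), function(i) {
    sc <- scores_by_cluster[[clusters[i]]]
    resampling_stage_test(sc, meta, ref_stage = stages[1], stages = comp_stages,
                          n_tests = n_tests, n_low = n_low, n_high = n_high,
                          seed = seeds[i])
  }, numeric(length(comp_stages))))
  dimnames(stage_p) <- list(clusters, comp_stages)
  stage_q <- matrix(bh_adjust(pmax(as.vector(stage_p), .Machine$double.xmin)),
                    nrow(stage_p), ncol(stage_p), dimnames = dimnames(stage_p))
  significant <- apply(stage_q < q_threshold, 1, any)

  dir_p <- function(sc, st, sx, sy, alt, sd_) {
    resampled_wilcox(sc, st, sx, sy, alt, n_tests, n_low, n_high, sd_)
  }
  cluster_module <- stats::setNames(rep("unassigned", length(clusters)), clusters)
  others <- setdiff(stages, climax_stage)
  succ <- cbind(stages[-length(stages)], stages[-1])
  for (i in seq_along(clusters)) {
    if (!significant[i]) next
    sc <- scores_by_cluster[[clusters[i]]]
    st <- meta$stage[match(names(sc) %||% meta$barcode, meta$barcode)]
    if (is.null(names(sc))) st <- meta$stage
    sd_i <- derive_seeds(seeds[i] + 1L, 4L)
    test_all <- function(pairs, alt, sd_) {
      all(vapply(seq_len(nrow(pairs)), function(j)
        dir_p(sc, st, pairs[j, 1], pairs[j, 2], alt, sd_ + j) < direction_alpha,
        logical(1)))
    }
    climax_pairs <- cbind(climax_stage, others)
    if (test_all(climax_pairs, "greater", sd_i[1])) {
      cluster_module[i] <- "1"
    } else if (test_all(climax_pairs, "less", sd_i[2])) {
      cluster_module[i] <- "2"
    } else if (test_all(succ[, c(2, 1), drop = FALSE], "less", sd_i[3])) {
      cluster_module[i] <- "3"
    } else if (test_all(succ[, c(2, 1), drop = FALSE], "greater", sd_i[4])) {
      cluster_module[i] <- "4"
    }
  }
  gene_cluster <- hard_clusters(fc)
  gene_module <- stats::setNames(cluster_module[gene_cluster], names(gene_cluster))
  structure(list(cluster_module = cluster_module, gene_module = gene_module,
                 stage_p = stage_p, stage_q = stage_q, significant = significant,
                 climax_stage = climax_stage),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat("ModuleAssignment:", sum(x$significant), "of", length(x$cluster_module),
      "clusters significant; modules:",
      paste(sprintf("%s=%d", names(table(x$cluster_module)), table(x$cluster_module)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Full trajectory-module pipeline for one cell population
#'
#' Convenience wrapper: stage-average the (optionally DEG-restricted)
#' genes, cluster with fuzzy c-means, score every cell for each cluster's
#' gene set, and classify clusters into the four modules.
#'
#' @param em [ExpressionMatrix()] (log2cp10k) for the cells of one cell type
#'   across stages.
#' @param meta metadata with `stage` (defaults to the matrix's own).
#' @param stages ordered stage labels.
#' @param n_clusters fuzzy c-means cluster count (15--30 for atlas-scale
#'   runs; smaller is fine for planted data).
#' @param genes optional gene subset (e.g. the union of stage DEGs).
#' @param m fuzzifier.
#' @param n_tests,n_low,n_high resampling controls.
#' @param q_threshold,direction_alpha classification thresholds.
#' @param n_bins,n_ctrl module-score controls.
#' @param seed master seed for clustering, scoring and resampling.
#' @return list: `clustering`, `assignment`, `scores` (per-cluster score
#'   vectors), `stage_profiles` (the standardized gene x stage matrix).
#' @export
run_trajectory_modules <- function(em, meta = NULL, stages, n_clusters,
                                   genes = NULL, m = 1.25, n_tests = 1000,
                                   n_low = 150, n_high = 1000,
                                   q_threshold = 1e-10, direction_alpha = 0.05,
                                   n_bins = 24, n_ctrl = 100, seed = 1) {
  meta <- meta %||% em$meta
  if (!is.null(genes)) {
    em <- ExpressionMatrix(em$values[, genes, drop = FALSE], em$normalization,
                           meta = meta)
  }
  X <- stage_average(em, meta, stages)
  fc <- fuzzy_cmeans(X, c = n_clusters, m = m, seed = seed)
  gene_cluster <- hard_clusters(fc)
  seeds <- derive_seeds(seed + 13L, ncol(fc$membership))
  scores <- stats::setNames(lapply(seq_len(ncol(fc$membership)), function(i) {
    cl <- colnames(fc$membership)[i]
    gs <- names(gene_cluster)[gene_cluster == cl]
    if (!length(gs)) return(stats::setNames(numeric(nrow(em$values)),
                                            rownames(em$values)))
    s <- module_score(em, gs, n_bins = n_bins, n_ctrl = n_ctrl, seed = seeds[i])
    stats::setNames(as.numeric(s), rownames(em$values))
  }), colnames(fc$membership))
  assignment <- classify_modules(fc, scores, meta, stages,
                                 q_threshold = q_threshold,
                                 direction_alpha = direction_alpha,
                                 n_tests = n_tests, n_low = n_low,
                                 n_high = n_high, seed = seed + 101L)
  list(clustering = fc, assignment = assignment, scores = scores,
       stage_profiles = X)
}

#' Cross-cell-type shared-gene frequencies per module
#'
#' Counts, for every gene and module, the number of cell types whose module
#' gene set contains that gene (the `freq` of Venn-style comparisons across
#' cell types).
#'
#' @param modules_by_celltype named list: cell type -> (module label ->
#'   character vector of genes).
#' @return data.frame(gene, module, freq) sorted by decreasing frequency
#'   (ties by module then gene). Genes absent everywhere do not appear.
#' @export
shared_gene_frequency <- function(modules_by_celltype) {
  rows <- list()
  for (ct in names(modules_by_celltype)) {
    mods <- modules_by_celltype[[ct]]
    for (m in names(mods)) {
      g <- unique(mods[[m]])
      if (length(g))
        rows[[paste(ct, m)]] <- data.frame(gene = g, module = m,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), module = character(0),
                      freq = integer(0), stringsAsFactors = FALSE))
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(list(freq = rep(1L, nrow(all))),
                          by = list(gene = all$gene, module = all$module), sum)
  agg <- agg[order(-agg$freq, agg$module, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
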