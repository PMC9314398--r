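# tiny NB two-stage expression fixture on the log2cp10k scale
two_stage_em <- function(n_per_stage, mu_a, mu_b, seed, disp = 0.4) {
  with_seed(seed, {
    nG <- length(mu_a)
    va <- matrix(rnbinom(n_per_stage * nG, mu = rep(mu_a, each = n_per_stage),
                         size = 1 / disp), n_per_stage, nG)
    vb <- matrix(rnbinom(n_per_stage * nG, mu = rep(mu_b, each = n_per_stage),
                         size = 1 / disp), n_per_stage, nG)
    v <- rbind(va, vb) + 0L
    storage.mode(v) <- "integer"
    dimnames(v) <- list(sprintf("c%04d", seq_len(2 * n_per_stage)),
                        sprintf("g%03d", seq_len(nG)))
    meta <- data.frame(barcode = rownames(v),
                       stage = rep(c("NF48", "NF54"), each = n_per_stage),
                       stringsAsFactors = FALSE)
    lognormalize(CountMatrix(v, meta = meta))
  })
}

test_that("internal-approximation Wilcoxon matches stats::wilcox.test", {
  wp <- getFromNamespace("wilcox_p", "scMetamorph")
  with_seed(10, {
    for (i in 1:20) {
      x <- rnorm(30); y <- rnorm(25, mean = runif(1, -1, 1))
      if (i %% 3 == 0) { x <- round(x); y <- round(y) }  # force ties
      for (alt in c("two.sided", "greater", "less")) {
        ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                                   exact = FALSE, correct = TRUE))
        expect_equal(wp(x, y, alt), ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("stage DEG calling honors min.pct, fold-change and BH gates", {
  base <- rep(20, 40)
  up <- base; up[1] <- 40          # planted 2-fold shift in g001
  em <- two_stage_em(300, up, base, seed = 12)
  degs <- find_stage_degs(em, stage_a = "NF48", stage_b = "NF54")
  expect_true("g001" %in% degs)
  st <- attr(degs, "stats")
  expect_true(all(abs(st$logfc[st$deg]) >= 0.1))
  # identical expression -> excluded (logfc = 0)
  expect_false("g002" %in% degs)
  # a gene detected in < 10% of cells in both stages is excluded regardless
  rare <- rep(0, 40); rare[3] <- 0.05
  em2 <- two_stage_em(300, rep(20, 40) + rare * 0, rep(20, 40), seed = 13)
  v <- em2$values; v[, 3] <- 0
  v[1:10, 3] <- 5   # ~3% detection, stage NF48 only
  em2$values <- v
  degs2 <- find_stage_degs(em2, stage_a = "NF48", stage_b = "NF54")
  expect_false("g003" %in% degs2)
  expect_true(is.na(attr(degs2, "stats")$p[3]))
  expect_error(find_stage_degs(em, stage_a = "NF48", stage_b = "missing"),
               "3 cells")
})

test_that("planted 2-fold shifts are recovered in >= 95% of seeds", {
  hits <- vapply(1:20, function(s) {
    base <- rep(15, 30); up <- base; up[1] <- 30
    em <- two_stage_em(300, up, base, seed = 100 + s)
    "g001" %in% find_stage_degs(em, stage_a = "NF48", stage_b = "NF54")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stage_average de-logs, re-logs and standardizes with exclusions", {
  # one cell per stage: averaged value is the de-log/re-log of that cell
  v <- matrix(c(3L, 1L, 9L, 7L, 0L, 7L), 2, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("gA", "gB", "gC")))
  meta <- data.frame(barcode = c("c1", "c2"), stage = c("NF48", "NF54"),
                     stringsAsFactors = FALSE)
  em <- lognormalize(CountMatrix(v, meta = meta))
  raw <- stage_average(em, stages = c("NF48", "NF54"), standardize = FALSE)
  expect_equal(raw[, "NF48"], setNames(em$values["c1", ], colnames(v)),
               tolerance = 1e-12)
  # brute-force loop oracle on a 5-gene toy with several cells per stage
  em5 <- two_stage_em(6, c(5, 9, 2, 7, 4), c(9, 9, 1, 2, 30), seed = 14)
  X <- stage_average(em5, stages = c("NF48", "NF54"), standardize = FALSE)
  st <- em5$meta$stage
  for (s in c("NF48", "NF54")) for (g in colnames(em5$values)) {
    cells <- em5$meta$barcode[st == s]
    expect_equal(X[g, s], log2(mean(2^em5$values[cells, g] - 1) + 1),
                 tolerance = 1e-12)
  }
  # constant gene excluded from the standardized matrix and flagged
  vcst <- cbind(v, gD = c(0L, 0L))
  emc <- lognormalize(CountMatrix(vcst, meta = meta))
  Z <- stage_average(emc, stages = c("NF48", "NF54"))
  expect_identical(attr(Z, "excluded"), "gD")
  expect_false("gD" %in% rownames(Z))
  expect_equal(unname(rowMeans(Z)), rep(0, nrow(Z)), tolerance = 1e-12)
})

test_that("fuzzy c-means obeys its algebraic guarantees", {
  with_seed(15, {
    X <- matrix(rnorm(200), 50, 4)
    rownames(X) <- paste0("g", 1:50)
    X <- t(scale(t(X)))
    for (s in 1:5) {
      fc <- fuzzy_cmeans(X, c = 3, seed = s)
      expect_equal(unname(rowSums(fc$membership)), rep(1, 50), tolerance = 1e-9)
      expect_true(all(fc$membership >= 0 & fc$membership <= 1))
      expect_true(all(diff(fc$objective_trace) <= 1e-8))
    }
  })
  # exact-zero distance from a center gives full membership there: two
  # duplicated locations converge to centers sitting exactly on the points
  X2 <- rbind(a = c(0, 0), b = c(0, 0), d = c(4, 4), e = c(4, 4))
  fc2 <- fuzzy_cmeans(X2, c = 2, seed = 1)
  hard <- apply(fc2$membership, 1, which.max)
  expect_equal(max(fc2$membership["a", ]), 1)
  expect_false(hard[["a"]] == hard[["d"]])
  expect_true(all(is.finite(fc2$membership)))
  # a point equidistant from both of 2 symmetric centers splits 50/50
  Xs <- rbind(a = c(-1, 0), b = c(-1, 0), d = c(1, 0), e = c(1, 0), mid = c(0, 0))
  fcs <- fuzzy_cmeans(Xs, c = 2, seed = 1, tol = 1e-10)
  expect_equal(unname(fcs$membership["mid", ]), c(0.5, 0.5), tolerance = 1e-6)
  expect_error(fuzzy_cmeans(Xs * NA, c = 2), "non-finite")
})

test_that("module_score is shift-invariant and matches hand computation", {
  v <- matrix(c(1, 2, 3,
                4, 0, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("gA", "gB", "gC")))
  meta <- data.frame(barcode = c("c1", "c2"), stringsAsFactors = FALSE)
  em <- ExpressionMatrix(v, "log2cp10k", meta = meta)
  # 1 bin, exhaustive controls: score = mean(set) - mean(all genes)
  s <- module_score(em, c("gA", "gB"), n_bins = 1, n_ctrl = 50, seed = 1)
  expect_equal(unname(s), rowMeans(v[, c("gA", "gB")]) - rowMeans(v),
               ignore_attr = TRUE)
  # control pool identical to the gene set -> score 0
  s0 <- module_score(ExpressionMatrix(v[, 1:2], "log2cp10k", meta = meta),
                     c("gA", "gB"), n_bins = 1, n_ctrl = 50, seed = 1)
  expect_equal(as.numeric(s0), c(0, 0))
  # adding a constant to every gene in a cell leaves its score unchanged
  v2 <- v; v2["c1", ] <- v["c1", ] + 5
  s2 <- module_score(ExpressionMatrix(v2, "log2cp10k", meta = meta),
                     c("gA", "gB"), n_bins = 1, n_ctrl = 50, seed = 1)
  expect_equal(unname(s2), unname(s), ignore_attr = TRUE)
  expect_error(module_score(em, character(0)), "empty gene set")
})

test_that("resampled stage test behaves under the null and under a shift", {
  with_seed(16, {
    n <- 8000   # stages well above n_high: subsamples are nearly independent
    meta <- data.frame(barcode = sprintf("c%04d", 1:(2 * n)),
                       stage = rep(c("NF48", "NF54"), each = n),
                       stringsAsFactors = FALSE)
    # identical distributions: averaged p stays large
    null_ok <- vapply(1:20, function(s) {
      scores <- setNames(with_seed(300 + s, rnorm(2 * n)), meta$barcode)
      resampling_stage_test(scores, meta, "NF48", n_tests = 100,
                            seed = s)[["NF54"]] >= 0.2
    }, logical(1))
    expect_gte(mean(null_ok), 0.95)
    # 2-pooled-SD location shift at 500 cells/stage: vanishing averaged p
    meta5 <- meta[c(1:500, n + 1:500), ]
    shifted <- setNames(c(rnorm(500), rnorm(500, mean = 2)), meta5$barcode)
    p <- resampling_stage_test(shifted, meta5, "NF48", n_tests = 50, seed = 1)
    expect_lt(p[["NF54"]], 1e-20)
    # single test with a fixed seed is reproducible
    p1 <- resampling_stage_test(shifted, meta5, "NF48", n_tests = 1, seed = 9)
    p2 <- resampling_stage_test(shifted, meta5, "NF48", n_tests = 1, seed = 9)
    expect_identical(p1, p2)
  })
})

test_that("planted archetypes classify into their modules (one seed)", {
  atlas <- generate_atlas(module_cfg(seed = 51))
  em <- lognormalize(filter_cells(atlas$counts))
  res <- run_trajectory_modules(em, stages = atlas$truth$stages,
                                n_clusters = 8, n_tests = 50, seed = 1)
  truth <- atlas$truth$module_archetype
  gm <- res$assignment$gene_module
  planted <- names(truth)[truth > 0]
  acc <- mean(gm[planted] == as.character(truth[planted]))
  expect_gte(acc, 0.9)
  # modules 1 and 2 never co-assigned; significance gate respected
  cm <- res$assignment$cluster_module
  expect_true(all(cm[!res$assignment$significant] == "unassigned"))
  expect_true(all(res$assignment$stage_q >= res$assignment$stage_p - 1e-15))
})

test_that("shared gene frequencies match a brute-force nested loop", {
  mods <- list(
    ct1 = list(`1` = c("zan", "a"), `4` = "b"),
    ct2 = list(`1` = c("zan"), `3` = "c"),
    ct3 = list(`1` = c("zan", "a")))
  out <- shared_gene_frequency(mods)
  expect_identical(out$freq[out$gene == "zan" & out$module == "1"], 3L)
  expect_identical(out$freq[out$gene == "a" & out$module == "1"], 2L)
  expect_false("absent" %in% out$gene)
  expect_true(all(diff(out$freq) <= 0))
  # brute force over random sets
  with_seed(17, {
    cts <- paste0("ct", 1:4)
    rand <- setNames(lapply(cts, function(ct)
      setNames(lapply(1:4, function(m) sample(letters[1:8], sample(0:4, 1))),
               as.character(1:4))), cts)
    out2 <- shared_gene_frequency(rand)
    for (i in seq_len(nrow(out2))) {
      cnt <- sum(vapply(cts, function(ct)
        out2$gene[i] %in% rand[[ct]][[out2$module[i]]], logical(1)))
      expect_identical(out2$freq[i], cnt)
    }
  })
  empty <- shared_gene_frequency(list())
  expect_identical(nrow(empty), 0L)
})
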