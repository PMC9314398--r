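# independent JSD oracle: entropy form H(m) - (H(p) + H(q))/2, direct summation
jsd_oracle <- function(p, q) {
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  H((p + q) / 2) - (H(p) + H(q)) / 2
}

random_simplex <- function(n) { x <- rexp(n); x / sum(x) }

test_that("jsd matches hand values, symmetry, identity and validation", {
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.311278, tolerance = 1e-6)
  p <- random_simplex(6)
  expect_equal(jsd(p, p), 0)
  with_seed(4, {
    for (i in 1:25) {
      a <- random_simplex(8); b <- random_simplex(8)
      expect_equal(jsd(a, b), jsd(b, a), tolerance = 1e-12)
      expect_equal(jsd(a, b), jsd_oracle(a, b), tolerance = 1e-12)
    }
  })
  expect_error(jsd(c(0.5, 0.5), c(0.7, 0.2)), "sum")
  expect_error(jsd(c(1.2, -0.2), c(0.5, 0.5)), "non-negative")
  expect_error(jsd(c(1), c(0.5, 0.5)), "length")
})

test_that("group_mean_profile equals a brute-force per-group mean", {
  with_seed(7, {
    v <- matrix(runif(60), 12, 5)
    dimnames(v) <- list(paste0("c", 1:12), paste0("g", 1:5))
    meta <- data.frame(barcode = rownames(v),
                       lineage = sample(c("a", "b", "c"), 12, replace = TRUE),
                       stringsAsFactors = FALSE)
    em <- ExpressionMatrix(v, "cp100k", meta = meta)
    prof <- group_mean_profile(em, group_key = "lineage")
    for (g in unique(meta$lineage)) for (j in 1:5)
      expect_equal(prof[j, g], mean(v[meta$lineage == g, j]))
    # log2cp10k input is de-logged before averaging
    eml <- ExpressionMatrix(log2(v + 1), "log2cp10k", meta = meta)
    expect_equal(group_mean_profile(eml, group_key = "lineage"), prof,
                 tolerance = 1e-12)
  })
})

test_that("specificity scores hit the concentration and uniform landmarks", {
  prof <- rbind(excl = c(8, 0, 0), unif2 = c(3, 3, 0), zero = c(0, 0, 0))
  colnames(prof) <- c("l1", "l2", "l3")
  st <- specificity_scores(prof)
  # exclusive gene: 1 in its group, 0 elsewhere (JSD of disjoint indicators = 1)
  expect_equal(unname(st$scores["excl", ]), c(1, 0, 0), tolerance = 1e-12)
  # uniform over 2 groups: 1 - sqrt(0.311278) in each
  expect_equal(unname(st$scores["unif2", 1:2]), rep(0.442078, 2), tolerance = 1e-5)
  # zero profile scored 0 everywhere and flagged
  expect_equal(unname(st$scores["zero", ]), c(0, 0, 0))
  expect_identical(st$flagged, "zero")
  expect_true(all(st$scores >= 0 & st$scores <= 1))
  expect_error(specificity_scores(prof[, 1, drop = FALSE]), "2 groups")
})

test_that("score is monotone in a group's share and permutation-equivariant", {
  # 1-parameter path: raise group 1's share, others proportional
  shares <- seq(0.2, 0.95, by = 0.05)
  s <- vapply(shares, function(a) {
    prof <- matrix(c(a, (1 - a) / 2, (1 - a) / 2), 1,
                   dimnames = list("g", c("l1", "l2", "l3")))
    specificity_scores(prof)$scores[1, 1]
  }, numeric(1))
  expect_true(all(diff(s) > 0))
  # permuting group labels permutes columns identically
  prof <- rbind(g1 = c(5, 1, 2), g2 = c(0, 4, 4))
  colnames(prof) <- c("l1", "l2", "l3")
  perm <- c(3, 1, 2)
  a <- specificity_scores(prof)$scores[, perm]
  b <- specificity_scores(prof[, perm])$scores
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("z-scoring standardizes rows and is idempotent", {
  prof <- rbind(g1 = c(0.9, 0.5, 0.1), g2 = c(0.4, 0.4, 0.4))
  colnames(prof) <- c("l1", "l2", "l3")
  st <- new_st <- structure(list(scores = prof, scale = "raw",
                                 group_kind = "lineage", groups = colnames(prof),
                                 raw = NULL, flagged = character(0)),
                            class = "SpecificityTable")
  z <- zscore_scores(st)
  expect_equal(unname(z$scores["g1", ]), c(1, 0, -1))   # sample sd 0.4
  expect_equal(unname(z$scores["g2", ]), c(0, 0, 0))    # constant row policy
  z2 <- zscore_scores(z)
  expect_equal(z2$scores, z$scores, tolerance = 1e-12)
})

test_that("call_specific_tfs ranks deterministically with documented tie-breaks", {
  prof <- rbind(a = c(6, 1), b = c(6, 1), c = c(1, 6))
  colnames(prof) <- c("l1", "l2")
  z <- zscore_scores(specificity_scores(prof))
  calls <- call_specific_tfs(z, k = 3)
  # a and b tie exactly: identifier order decides
  expect_identical(calls$l1$gene[1:2], c("a", "b"))
  # k = TF count lists every TF once per group
  expect_identical(sort(calls$l1$gene), c("a", "b", "c"))
  expect_warning(call_specific_tfs(z, k = 10), "exceeds")
})

test_that("conserved TFs require an ortholog in every species' call set", {
  calls <- list(
    frog  = list(gut = c("a1", "a2", "a3")),
    spB   = list(gut = c("b1")),
    spC   = list(gut = c("c2")))
  maps <- list(data.frame(
    species_a = "frog", gene_a = c("a1", "a1", "a1", "a2"),
    species_b = c("spB", "spC", "spC", "spB"),
    gene_b = c("b1", "c1", "c2", "b9"),
    relation = c("one2one", "one2many", "one2many", "one2one"),
    stringsAsFactors = FALSE))
  out <- conserved_tfs(calls, maps, "frog")
  # a1: b1 called in B, and one of {c1, c2} (c2) called in C -> conserved
  # a2: ortholog b9 not called; a3: no orthologs at all
  expect_identical(out$gut, "a1")
  # empty call set anywhere empties the result
  calls$spB$gut <- character(0)
  expect_identical(conserved_tfs(calls, maps, "frog")$gut, character(0))
  expect_error(conserved_tfs(calls[c("frog", "spB")],
                             list(maps[[1]][0, ]), "frog"), "no ortholog map")
})

test_that("planted single-lineage TFs score high and are recovered (one seed)", {
  atlas <- generate_atlas(small_cfg(seed = 31, n_empty_barcodes = 400))
  corrected <- corrected_cells(atlas)
  em <- lognormalize(corrected)
  prof <- group_mean_profile(em, group_key = "lineage")
  tfs <- grep("^TF", rownames(prof), value = TRUE)
  st <- specificity_scores(prof, tfs = tfs)
  for (l in names(atlas$truth$planted_tf_sets)) {
    planted <- atlas$truth$planted_tf_sets[[l]]
    expect_true(all(st$scores[planted, l] >= 0.7))
  }
  calls <- call_specific_tfs(zscore_scores(st), k = 5)
  for (l in names(atlas$truth$planted_tf_sets))
    expect_true(all(atlas$truth$planted_tf_sets[[l]] %in% calls[[l]]$gene))
})
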