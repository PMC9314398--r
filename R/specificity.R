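#' Jensen-Shannon divergence (base 2)
#'
#' Symmetric, bounded divergence between two probability vectors:
#' `JSD(p, q) = (KL(p || m) + KL(q || m)) / 2` with `m = (p + q) / 2` and
#' logarithms base 2, so the value lies in \[0, 1\]. Terms with a zero
#' numerator contribute zero.
#'
#' @param p,q non-negative numeric vectors of equal length summing to 1
#'   (within 1e-9).
#' @return The divergence, a single number in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("probability vectors must sum to 1 (within 1e-9)")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  val <- (kl(p) + kl(q)) / 2
  min(max(val, 0), 1)
}

#' Mean expression profile per group
#'
#' @param em an [ExpressionMatrix()]; log2cp10k values are de-logged so the
#'   mean is taken on the linear normalized scale.
#' @param meta per-barcode metadata (defaults to the matrix's own).
#' @param group_key metadata field defining groups (e.g. `"lineage"`,
#'   `"cell_type"`).
#' @return A gene x group matrix of mean linear-scale expression.
#' @export
group_mean_profile <- function(em, meta = NULL, group_key = "lineage") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  meta <- meta %||% em$meta
  labels <- meta[[group_key]][match(rownames(em$values), meta$barcode)]
  if (anyNA(labels))
    stop("missing ", group_key, " labels for ", sum(is.na(labels)), " barcodes")
  v <- linear_values(em)
  groups <- sort(unique(labels))
  prof <- vapply(groups, function(g) colMeans(v[labels == g, , drop = FALSE]),
                 numeric(ncol(v)))
  if (any(table(labels) == 0)) stop("empty group")
  rownames(prof) <- colnames(v)
  prof
}

new_specificity_table <- function(scores, scale, group_kind, raw = NULL,
                                  flagged = character(0)) {
  structure(list(scores = scores, scale = scale, group_kind = group_kind,
                 groups = colnames(scores), raw = raw, flagged = flagged),
            class = "SpecificityTable")
}

#' @export
print.SpecificityTable <- function(x, ...) {
  cat(sprintf("SpecificityTable (%s, %s): %d genes x %d groups\n",
              x$scale, x$group_kind, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' TF specificity scores from Jensen-Shannon divergence
#'
#' For each gene its cross-group expression profile is normalized to a
#' probability vector `p_g`, and the specificity score for group `l` is
#' `1 - sqrt(JSD(p_g, e_l))` where `e_l` is the indicator distribution of
#' that group. A score of 1 means the gene is exactly group-exclusive; the
#' base-2 JSD bounds scores to \[0, 1\]. Genes with an all-zero profile get
#' score 0 everywhere and are flagged.
#'
#' @param profile gene x group matrix of mean expression (see
#'   [group_mean_profile()]).
#' @param tfs genes to score (default all rows); typically an externally
#'   supplied TF list.
#' @param group_kind label recorded in the result (`"lineage"` or
#'   `"cell_type"`).
#' @return A raw-scale `SpecificityTable`; zero-profile genes are listed in
#'   its `flagged` element.
#' @export
specificity_scores <- function(profile, tfs = rownames(profile),
                               group_kind = "lineage") {
  stopifnot(is.matrix(profile))
  if (ncol(profile) < 2) stop("at least 2 groups are required")
  missing <- setdiff(tfs, rownames(profile))
  if (length(missing))
    stop("genes absent from profile: ", paste(utils::head(missing, 5), collapse = ", "))
  prof <- profile[tfs, , drop = FALSE]
  G <- ncol(prof)
  scores <- matrix(0, nrow(prof), G, dimnames = dimnames(prof))
  tot <- rowSums(prof)
  flagged <- rownames(prof)[tot == 0]
  if (length(flagged))
    log_msg(length(flagged), " gene(s) with all-zero profile scored 0 and flagged")
  for (g in which(tot > 0)) {
    p <- prof[g, ] / tot[g]
    for (l in seq_len(G)) {
      e <- numeric(G)
      e[l] <- 1
      scores[g, l] <- 1 - sqrt(jsd(p, e))
    }
  }
  new_specificity_table(scores, "raw", group_kind, flagged = flagged)
}

#' Z-score-normalize specificity scores
#'
#' Each gene's scores are standardized across groups ((x - mean) / sd, with
#' sample sd). A constant row becomes all zeros. The raw scores are kept in
#' the result (`$raw`) for tie-breaking in downstream calls. Z-scored rows
#' re-z-score to themselves.
#'
#' @param st a raw-scale `SpecificityTable`.
#' @return A zscore-scale `SpecificityTable`.
#' @export
zscore_scores <- function(st) {
  stopifnot(inherits(st, "SpecificityTable"))
  raw <- if (st$scale == "raw") st$scores else st$raw
  z <- t(apply(st$scores, 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(st$scores)
  new_specificity_table(z, "zscore", st$group_kind, raw = raw, flagged = st$flagged)
}

#' Call group-specific TFs from z-scored specificity
#'
#' Per group, genes are ranked by z-score (descending), ties broken by raw
#' score and then gene identifier, and the top `k` are called (optionally
#' additionally requiring z >= `z_threshold`).
#'
#' @param st a zscore-scale `SpecificityTable` (from [zscore_scores()]).
#' @param k calls per group (default 20); a `k` above the TF count yields a
#'   truncated list with a warning.
#' @param z_threshold optional minimum z-score.
#' @return Named list: group -> data.frame(gene, zscore, raw), ranked.
#' @export
call_specific_tfs <- function(st, k = 20, z_threshold = NULL) {
  stopifnot(inherits(st, "SpecificityTable"))
  if (st$scale != "zscore") stop("call_specific_tfs expects z-scored input")
  if (k > nrow(st$scores)) {
    warning("k = ", k, " exceeds the TF count; returning all ", nrow(st$scores))
    k <- nrow(st$scores)
  }
  raw <- st$raw %||% st$scores
  out <- list()
  for (g in colnames(st$scores)) {
    z <- st$scores[, g]
    ord <- order(-z, -raw[, g], rownames(st$scores))
    df <- data.frame(gene = rownames(st$scores)[ord], zscore = z[ord],
                     raw = raw[ord, g], stringsAsFactors = FALSE)
    rownames(df) <- NULL
    if (!is.null(z_threshold)) df <- df[df$zscore >= z_threshold, , drop = FALSE]
    out[[g]] <- utils::head(df, k)
  }
  out
}

#' Cross-species conserved specific TFs
#'
#' An anchor-species TF is conserved in a group if, for every other species,
#' at least one of its orthologs (one2one or one2many) appears in that
#' species' call set for the same group.
#'
#' @param calls_by_species named list: species -> (group -> character vector
#'   of called TFs). Accepts the data.frame lists from
#'   [call_specific_tfs()] as well.
#' @param maps list of ortholog tables, data.frames with columns
#'   `species_a`, `gene_a`, `species_b`, `gene_b`, `relation`
#'   (`one2one`/`one2many`); direction is ignored. Together they must
#'   connect the anchor to every other species.
#' @param anchor_species species whose TFs are reported.
#' @return Named list: group -> character vector of conserved anchor TFs.
#' @export
conserved_tfs <- function(calls_by_species, maps, anchor_species) {
  stopifnot(anchor_species %in% names(calls_by_species))
  as_sets <- function(calls) lapply(calls, function(x)
    if (is.data.frame(x)) x$gene else as.character(x))
  calls_by_species <- lapply(calls_by_species, as_sets)
  others <- setdiff(names(calls_by_species), anchor_species)
  maps <- lapply(maps, function(m) {
    stopifnot(all(c("species_a", "gene_a", "species_b", "gene_b") %in% names(m)))
    m
  })
  # per other species: anchor gene -> orthologs, from either direction
  ortho <- list()
  for (sp in others) {
    pairs <- do.call(rbind, lapply(maps, function(m) {
      fwd <- m[m$species_a == anchor_species & m$species_b == sp,
               c("gene_a", "gene_b")]
      rev <- m[m$species_b == anchor_species & m$species_a == sp,
               c("gene_b", "gene_a")]
      names(rev) <- c("gene_a", "gene_b")
      rbind(fwd, rev)
    }))
    if (is.null(pairs) || nrow(pairs) == 0)
      stop("no ortholog map connects '", anchor_species, "' to '", sp, "'")
    ortho[[sp]] <- split(pairs$gene_b, pairs$gene_a)
  }
  groups <- names(calls_by_species[[anchor_species]])
  out <- list()
  for (grp in groups) {
    anchor_set <- calls_by_species[[anchor_species]][[grp]]
    keep <- vapply(anchor_set, function(tf) {
      all(vapply(others, function(sp) {
        orth <- ortho[[sp]][[tf]]
        length(orth) > 0 &&
          length(intersect(orth, calls_by_species[[sp]][[grp]] %||% character(0))) > 0
      }, logical(1)))
    }, logical(1))
    out[[grp]] <- anchor_set[keep]
  }
  out
}
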