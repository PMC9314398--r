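#' Within-stage TF specificity across cell types
#'
#' Computes, for one developmental stage, the raw JSD specificity score of
#' every TF against each cell type: `Y(g, a) = 1 - sqrt(JSD(p_g, e_a))`
#' with `p_g` the TF's normalized profile across the stage's cell types.
#' TFs with zero expression at the stage are dropped (flagged), rather than
#' scored zero, so the driver score compares only TFs present at both
#' stages.
#'
#' @param em_stage an [ExpressionMatrix()] restricted to one stage's cells.
#' @param meta per-barcode metadata with `cell_type` set (defaults to the
#'   matrix's own).
#' @param tfs TF gene identifiers to score.
#' @return A raw-scale `SpecificityTable` over cell types; zero-expression
#'   TFs are removed from the rows and listed in `$flagged`.
#' @export
stage_specificity <- function(em_stage, meta = NULL, tfs) {
  prof <- group_mean_profile(em_stage, meta, group_key = "cell_type")
  if (ncol(prof) < 2) stop("a stage must contain at least 2 cell types")
  st <- specificity_scores(prof, tfs = tfs, group_kind = "cell_type")
  if (length(st$flagged)) {
    st$scores <- st$scores[setdiff(rownames(st$scores), st$flagged), , drop = FALSE]
    log_msg("dropped ", length(st$flagged), " zero-expression TF(s) from the stage")
  }
  st
}

#' Driver-TF score for a matched cell type at two stages
#'
#' Combines a cell type's per-TF specificity at two stages:
#' `h = T(S(y1)) * T(S(y2))` elementwise, where `S` standardizes to zero
#' mean and unit variance (sample sd; a constant vector standardizes to
#' zeros) and `T` truncates negative values to zero to ignore weakly
#' specific TFs. `h >= 0` always, and `h = 0` whenever a TF is at or below
#' the mean specificity at either stage. Only TFs present in both vectors
#' are scored.
#'
#' @param y1,y2 named per-TF raw specificity vectors for the matched cell
#'   type at stage 1 and stage 2 (columns of [stage_specificity()] tables).
#' @return Named numeric vector `h` over the common TFs, with attribute
#'   `"ysum"` (`y1 + y2`, used for tie-breaking).
#' @export
driver_score <- function(y1, y2) {
  common <- intersect(names(y1), names(y2))
  if (length(common) < 3) stop("fewer than 3 TFs shared between stages; sd is unstable")
  y1 <- y1[common]; y2 <- y2[common]
  std <- function(y) {
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) rep(0, length(y)) else (y - mean(y)) / s
  }
  h <- pmax(0, std(y1)) * pmax(0, std(y2))
  names(h) <- common
  attr(h, "ysum") <- y1 + y2
  h
}

#' Top driver TFs
#'
#' Ranks TFs by the driver score `h` (descending), ties broken by the sum of
#' the two stage specificities and then the gene identifier. TFs with
#' `h = 0` appear only when fewer than `k` have `h > 0`, and are flagged.
#'
#' @param h driver score vector from [driver_score()].
#' @param k list length (default 5).
#' @param ysum tie-break vector (defaults to the attribute carried by `h`).
#' @return data.frame(gene, h, flagged) of up to `k` rows.
#' @export
top_driver_tfs <- function(h, k = 5, ysum = NULL) {
  ysum <- ysum %||% attr(h, "ysum") %||% stats::setNames(numeric(length(h)), names(h))
  ord <- order(-h, -ysum[names(h)], names(h))
  df <- data.frame(gene = names(h)[ord], h = as.numeric(h[ord]),
                   stringsAsFactors = FALSE)
  df$flagged <- df$h <= 0
  # sorted by h descending, so h = 0 rows enter only when < k have h > 0
  out <- utils::head(df, min(k, nrow(df)))
  rownames(out) <- NULL
  out
}

#' End-to-end driver-TF analysis for one cell type across two stages
#'
#' Cell types are matched across stages by identical annotation label (or an
#' explicit `pairing`). Runs [stage_specificity()] at both stages, extracts
#' the matched columns, and ranks by [driver_score()].
#'
#' @param em1,em2 [ExpressionMatrix()] objects for the two stages.
#' @param meta1,meta2 metadata (default: carried by the matrices).
#' @param tfs TF identifiers.
#' @param cell_type cell type label at stage 1.
#' @param cell_type2 matched label at stage 2 (default: same label).
#' @param k number of driver TFs to report.
#' @return list with `y1`, `y2`, `h` and `top` (the ranked data.frame).
#' @export
driver_tf_analysis <- function(em1, em2, meta1 = NULL, meta2 = NULL, tfs,
                               cell_type, cell_type2 = cell_type, k = 5) {
  st1 <- stage_specificity(em1, meta1, tfs)
  st2 <- stage_specificity(em2, meta2, tfs)
  if (!cell_type %in% colnames(st1$scores))
    stop("cell type '", cell_type, "' absent from stage 1")
  if (!cell_type2 %in% colnames(st2$scores))
    stop("cell type '", cell_type2, "' absent from stage 2")
  y1 <- st1$scores[, cell_type]
  y2 <- st2$scores[, cell_type2]
  h <- driver_score(y1, y2)
  list(y1 = y1, y2 = y2, h = h, top = top_driver_tfs(h, k = k))
}
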