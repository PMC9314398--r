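#' Filter barcodes by transcript count
#'
#' Quality-control rule: keep exactly the barcodes in which at least
#' `min_transcripts` transcripts were detected (barcodes with fewer are
#' removed; the inequality is strict on the low side, so a 500-UMI barcode
#' survives the default threshold).
#'
#' @param cm a [CountMatrix()].
#' @param min_transcripts minimum row total to keep (default 500).
#' @return The filtered `CountMatrix`, barcode order preserved. Removing
#'   every barcode is a warning, not an error.
#' @export
filter_cells <- function(cm, min_transcripts = 500) {
  stopifnot(inherits(cm, "CountMatrix"))
  keep <- rowSums(cm$values) >= min_transcripts
  if (!any(keep)) warning("all barcodes fall below the transcript threshold")
  cm[keep, TRUE]
}

#' Estimate the batch gene background from empty barcodes
#'
#' Cell barcodes with fewer than `umi_threshold` UMIs are taken to be empty
#' beads exposed to cell-free RNA; the background value of each gene is its
#' arithmetic mean count over those sub-threshold barcodes of one batch.
#' Must be run on the unfiltered matrix.
#'
#' @param cm_all the unfiltered [CountMatrix()] (sub-threshold barcodes
#'   still present).
#' @param umi_threshold barcodes below this total form the background
#'   (default 500).
#' @param batch batch label to restrict to; may be omitted when the matrix
#'   holds a single batch (or no batch metadata).
#' @return A `BackgroundProfile` with `bg_mean` (per-gene mean), `prevalence`
#'   (fraction of background barcodes detecting each gene),
#'   `n_background_barcodes`, `batch` and `umi_threshold`.
#' @export
estimate_background_profile <- function(cm_all, umi_threshold = 500, batch = NULL) {
  stopifnot(inherits(cm_all, "CountMatrix"))
  bt <- cm_all$meta$batch
  if (is.null(batch)) {
    known <- unique(bt[!is.na(bt)])
    if (length(known) > 1)
      stop("multiple batches present; estimate one profile per batch (supply `batch`)")
    batch <- if (length(known)) known else NA_character_
  } else {
    cm_all <- cm_all[!is.na(bt) & bt == batch, TRUE]
  }
  sub <- rowSums(cm_all$values) < umi_threshold
  if (!any(sub))
    stop("no barcodes below ", umi_threshold,
         " UMIs; supply the unfiltered matrix (background cannot be estimated from filtered cells)")
  m <- cm_all$values[sub, , drop = FALSE]
  structure(list(batch = batch, umi_threshold = umi_threshold,
                 bg_mean = colMeans(m),
                 prevalence = colMeans(m > 0),
                 n_background_barcodes = sum(sub)),
            class = "BackgroundProfile")
}

#' @export
print.BackgroundProfile <- function(x, ...) {
  cat(sprintf("BackgroundProfile: batch %s, %d background barcodes (< %d UMIs), %d/%d genes with background > 0\n",
              x$batch, x$n_background_barcodes, x$umi_threshold,
              sum(x$bg_mean > 0), length(x$bg_mean)))
  invisible(x)
}

#' Subtract the batch gene background from each cell
#'
#' For each cell, the per-gene background mean is rescaled by the median
#' fold difference between the cell's detected expression and the empty-bead
#' means (ratios taken over genes with positive background, zeros included),
#' rounded to the nearest integer (halves away from zero), and subtracted
#' with clipping at zero. Genes with zero background mean are untouched and
#' the result stays integer-valued, within `[0, observed]`.
#'
#' @param cm the (typically filtered) [CountMatrix()] to correct; gene order
#'   must match the profile.
#' @param profile a [estimate_background_profile()] result from the same
#'   batch. Correction never crosses batch boundaries: if the matrix carries
#'   batch labels, all cells must belong to the profile's batch.
#' @param min_prevalence optional prevalence filter: only genes detected in
#'   at least this fraction of background barcodes are treated as batch
#'   genes (default 0 = off).
#' @return The corrected `CountMatrix`; per-cell scale factors are attached
#'   as attribute `"scale"`.
#' @export
correct_background <- function(cm, profile, min_prevalence = 0) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(profile, "BackgroundProfile"))
  if (!identical(colnames(cm$values), names(profile$bg_mean)))
    stop("profile gene order does not match the count matrix")
  bt <- unique(cm$meta$batch[!is.na(cm$meta$batch)])
  if (length(bt) && !is.na(profile$batch) && !all(bt == profile$batch))
    stop("count matrix contains batches other than the profile's ('",
         profile$batch, "'); correct each batch with its own profile")
  bg <- profile$bg_mean
  pos <- bg > 0 & profile$prevalence >= min_prevalence
  if (!any(pos)) {
    warning("background mean is zero for every gene; returning input unchanged")
    return(cm)
  }
  folds <- sweep(cm$values[, pos, drop = FALSE], 2, bg[pos], "/")
  scale <- apply(folds, 1, stats::median)
  backg <- round_half_away(outer(scale, bg[pos]))
  v <- cm$values
  v[, pos] <- pmax(0L, v[, pos, drop = FALSE] - backg)
  storage.mode(v) <- "integer"
  out <- cm
  out$values <- v
  attr(out, "scale") <- stats::setNames(scale, rownames(v))
  out
}
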