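#' Aggregate cells of a type into pseudocells
#'
#' Pseudocells denoise cross-species comparisons: within each cell type,
#' barcodes are shuffled (seeded) and partitioned into consecutive groups of
#' `group_size`; each pseudocell is the arithmetic mean of its members on
#' the linear normalized scale. The trailing remainder group is kept only if
#' it has at least `min_size` members (dropped with a warning otherwise).
#'
#' @param em an [ExpressionMatrix()], expected on the `cp100k` scale (a
#'   warning is emitted otherwise); means then stay on the 100,000-total
#'   simplex.
#' @param meta per-barcode metadata with the grouping field set; defaults to
#'   the metadata carried by `em`.
#' @param group_size cells per pseudocell (default 50).
#' @param min_size minimum size of the remainder group (default 10).
#' @param group_key metadata field to group by (default `"cell_type"`).
#' @param seed shuffle seed.
#' @return An object of class `PseudocellMatrix` with `values`
#'   (pseudocell x gene), `members` (list of member barcodes) and
#'   `group_key`.
#' @export
make_pseudocells <- function(em, meta = NULL, group_size = 50, min_size = 10,
                             group_key = "cell_type", seed = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"), group_size >= 1)
  if (em$normalization != "cp100k")
    warning("pseudocells are intended for cp100k input; got ", em$normalization)
  meta <- meta %||% em$meta
  labels <- meta[[group_key]][match(rownames(em$values), meta$barcode)]
  if (anyNA(labels))
    stop("missing ", group_key, " labels for barcodes: ",
         paste(utils::head(rownames(em$values)[is.na(labels)], 5), collapse = ", "))
  types <- sort(unique(labels))
  rows <- list(); members <- list()
  for (ct in types) {
    bc <- rownames(em$values)[labels == ct]
    bc <- with_seed(seed, sample(bc))
    starts <- seq(1, length(bc), by = group_size)
    for (i in seq_along(starts)) {
      grp <- bc[starts[i]:min(starts[i] + group_size - 1, length(bc))]
      if (length(grp) < min_size && length(starts) > 1) {
        warning(sprintf("dropping remainder group of %d < %d cells for '%s'",
                        length(grp), min_size, ct))
        next
      }
      id <- sprintf("%s_ps%d", ct, i)
      rows[[id]] <- colMeans(em$values[grp, , drop = FALSE])
      members[[id]] <- grp
    }
  }
  if (!length(rows)) stop("no pseudocells formed")
  values <- do.call(rbind, rows)
  structure(list(values = values, members = members, group_key = group_key),
            class = "PseudocellMatrix")
}

#' Randomly subsample barcodes
#'
#' Optional pre-subsampling step (e.g. a fixed number of cells per species
#' before pseudocell construction).
#'
#' @param cm a [CountMatrix()] or [ExpressionMatrix()].
#' @param n number of barcodes to keep; if `n >=` the barcode count the
#'   object is returned unchanged.
#' @param seed sampling seed.
#' @return The subsetted object (barcode order preserved).
#' @export
subsample_cells <- function(cm, n, seed = 1) {
  bc <- rownames(cm$values)
  if (n >= length(bc)) return(cm)
  keep <- sort(with_seed(seed, sample(length(bc), n)))
  cm$values <- cm$values[keep, , drop = FALSE]
  cm$meta <- cm$meta[match(rownames(cm$values), cm$meta$barcode), , drop = FALSE]
  rownames(cm$meta) <- NULL
  cm
}
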