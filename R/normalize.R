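#' Normalized expression matrix
#'
#' @param values numeric barcode x gene matrix.
#' @param normalization `"log2cp10k"` for `log2(CPM/100 + 1)` values or
#'   `"cp100k"` for counts scaled to 100,000 per barcode.
#' @param meta per-barcode metadata data.frame (carried along from the
#'   source `CountMatrix`).
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, normalization = c("log2cp10k", "cp100k"),
                             meta = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, normalization = normalization,
                 meta = meta %||% empty_meta(rownames(values))),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d barcodes x %d genes\n",
              x$normalization, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Log-normalize counts as log2(CPM/100 + 1)
#'
#' The per-dataset normalization used before clustering and all log-scale
#' analyses: counts per million divided by 100 (i.e. counts per 10,000),
#' plus one, log base 2. Values are invariant to each barcode's total depth.
#'
#' @param cm a [CountMatrix()], already filtered of zero-total barcodes.
#' @return An [ExpressionMatrix()] with `normalization = "log2cp10k"`.
#' @export
lognormalize <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  tot <- rowSums(cm$values)
  if (any(tot == 0))
    stop("zero-total barcode(s): ",
         paste(utils::head(rownames(cm$values)[tot == 0], 5), collapse = ", "),
         "; filter before normalizing")
  v <- log2(cm$values / tot * 1e4 + 1)
  ExpressionMatrix(v, "log2cp10k", meta = cm$meta)
}

#' Scale counts to a fixed total per barcode
#'
#' Normalization to the sum of transcripts, multiplied by 100,000 --- the
#' linear-scale input used for pseudocell construction and cross-species
#' comparison prep.
#'
#' @param cm a [CountMatrix()] without zero-total barcodes.
#' @param target row total after scaling (default 100,000).
#' @return An [ExpressionMatrix()] with `normalization = "cp100k"`.
#' @export
total_normalize <- function(cm, target = 1e5) {
  stopifnot(inherits(cm, "CountMatrix"))
  tot <- rowSums(cm$values)
  if (any(tot == 0))
    stop("zero-total barcode(s): ",
         paste(utils::head(rownames(cm$values)[tot == 0], 5), collapse = ", "))
  v <- cm$values / tot * target
  ExpressionMatrix(v, "cp100k", meta = cm$meta)
}

# linear-scale values for averaging: de-log log2cp10k, pass cp100k through
linear_values <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$normalization == "log2cp10k") 2^em$values - 1 else em$values
}
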