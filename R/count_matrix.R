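#' UMI count matrix with per-barcode metadata
#'
#' Container for raw droplet data: an integer barcode x gene matrix of UMI
#' counts plus a per-barcode metadata table (batch, developmental stage,
#' tissue, cell type, lineage). Metadata fields that are unknown are `NA`,
#' never the empty string.
#'
#' @param values integer matrix, barcodes as rows (rownames), genes as
#'   columns (colnames). All entries must be non-negative integers.
#' @param meta optional data.frame keyed by a `barcode` column; missing
#'   fields are filled with `NA`.
#' @return An object of class `CountMatrix` with elements `values` and
#'   `meta` (one row per barcode, in matrix order).
#' @export
CountMatrix <- function(values, meta = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs barcode rownames and gene colnames")
  if (anyDuplicated(rownames(values))) stop("barcode identifiers must be unique")
  if (anyDuplicated(colnames(values))) stop("gene identifiers must be unique")
  if (any(!is.finite(values)) || any(values < 0) ||
      any(values != floor(values)))
    stop("counts must be non-negative integers")
  storage.mode(values) <- "integer"
  cm <- structure(list(values = values, meta = empty_meta(rownames(values))),
                  class = "CountMatrix")
  if (!is.null(meta)) cm <- attach_metadata(cm, meta)
  cm
}

meta_fields <- c("batch", "stage", "tissue", "cell_type", "lineage")

empty_meta <- function(barcodes) {
  df <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  for (f in meta_fields) df[[f]] <- NA_character_
  rownames(df) <- NULL
  df
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d barcodes x %d genes, %d UMIs total\n",
              nrow(x$values), ncol(x$values), sum(as.numeric(x$values))))
  known <- colSums(!is.na(x$meta[meta_fields]))
  cat("metadata set for:", paste(sprintf("%s (%d)", names(known)[known > 0],
                                         known[known > 0]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Subset a CountMatrix by barcode and/or gene
#'
#' @param x a `CountMatrix`.
#' @param i,j barcode / gene indices (any form `[` accepts).
#' @param ... ignored.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  out <- structure(list(values = v, meta = NULL), class = "CountMatrix")
  out$meta <- x$meta[match(rownames(v), x$meta$barcode), , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Read a UMI count matrix
#'
#' Reads either a CellRanger-style Matrix Market triplet (`matrix.mtx` with
#' genes as rows on disk, plus `barcodes.tsv` and `genes.tsv`) or a dense CSV
#' with barcodes in the first column and genes in the header. The in-memory
#' orientation is always barcode x gene; entries absent from the sparse file
#' are zero. Metadata starts empty; see [attach_metadata()].
#'
#' @param path for `mtx_triplet`, a directory holding the three files; for
#'   `dense_csv`, the CSV file.
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @return A [CountMatrix()].
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_csv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    bcf <- file.path(path, "barcodes.tsv")
    gnf <- file.path(path, "genes.tsv")
    for (f in c(mtx, bcf, gnf)) if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    barcodes <- readLines(bcf)
    genes <- readLines(gnf)
    if (nrow(m) != length(genes))
      stop(sprintf("dimension mismatch: matrix.mtx has %d rows but genes.tsv has %d entries",
                   nrow(m), length(genes)))
    if (ncol(m) != length(barcodes))
      stop(sprintf("dimension mismatch: matrix.mtx has %d columns but barcodes.tsv has %d entries",
                   ncol(m), length(barcodes)))
    v <- t(as.matrix(m))
    if (any(v != floor(v))) stop("matrix.mtx contains non-integer entries")
    dimnames(v) <- list(barcodes, genes)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    v <- as.matrix(df)
    if (!is.numeric(v) || any(v != floor(v)))
      stop("dense CSV contains non-integer entries")
    dimnames(v) <- list(rownames(df), colnames(df))
  }
  CountMatrix(v)
}

#' Write a CountMatrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx` (1-based coordinate triplet, genes as rows on disk,
#' noted in a header comment), `barcodes.tsv` and `genes.tsv` under `dir`.
#'
#' @param cm a `CountMatrix`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(cm$values), sparse = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  lines <- readLines(mtx)
  writeLines(c(lines[1],
               "% genes as rows on disk; transposed to barcode x gene in memory",
               lines[-1]), mtx)
  writeLines(rownames(cm$values), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(cm$values), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Attach per-barcode metadata to a CountMatrix
#'
#' @param cm a `CountMatrix`.
#' @param table data.frame with a `barcode` column and any of `batch`,
#'   `stage`, `tissue`, `cell_type`, `lineage`. Barcodes absent from the
#'   table keep `NA` fields; table rows for unknown barcodes are ignored
#'   with a warning. Duplicate barcode keys are an error.
#' @return The `CountMatrix` with `meta` filled in.
#' @export
attach_metadata <- function(cm, table) {
  stopifnot(inherits(cm, "CountMatrix"), is.data.frame(table))
  if (!"barcode" %in% names(table)) stop("metadata table needs a 'barcode' column")
  if (anyDuplicated(table$barcode))
    stop("duplicate barcode keys in metadata table: ",
         paste(unique(table$barcode[duplicated(table$barcode)]), collapse = ", "))
  unknown <- setdiff(table$barcode, rownames(cm$values))
  if (length(unknown)) {
    warning(length(unknown), " metadata rows refer to unknown barcodes and were ignored")
    log_msg("ignored unknown barcodes: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  meta <- cm$meta %||% empty_meta(rownames(cm$values))
  idx <- match(meta$barcode, table$barcode)
  for (f in intersect(meta_fields, names(table))) {
    val <- as.character(table[[f]])[idx]
    meta[[f]] <- ifelse(is.na(idx), meta[[f]], val)
  }
  # explicit NA for blanks: missing metadata is never the empty string
  for (f in meta_fields) meta[[f]][!is.na(meta[[f]]) & meta[[f]] == ""] <- NA_character_
  cm$meta <- meta
  cm
}

#' Write a result table to disk
#'
#' Serializes the package's result objects (plain data.frames,
#' `SpecificityTable`, `ModuleAssignment`, or any list) so that
#' [read_table()] returns an equal object.
#'
#' @param obj object to write.
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (inherits(obj, "SpecificityTable")) {
    obj <- data.frame(gene = rownames(obj$scores), obj$scores,
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(obj, "ModuleAssignment")) {
    if (format != "json") stop("ModuleAssignment is written as JSON")
    obj <- unclass(obj)
  }
  if (format == "json") {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                         dataframe = "columns", matrix = "rowmajor")
  } else {
    sep <- if (format == "tsv") "\t" else ","
    utils::write.table(obj, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file to read.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return data.frame for tsv/csv; list for json.
#' @export
read_table <- function(path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (format == "json") return(jsonlite::read_json(path, simplifyVector = TRUE))
  sep <- if (format == "tsv") "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
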