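#' One-sided hypergeometric gene-set over-representation
#'
#' For each term with `K` genes in the universe (`N` genes), a query of `n`
#' genes overlapping the term in `k` genes is scored with the upper-tail
#' hypergeometric probability `P(X >= k)` (so `k = 0` gives p = 1), followed
#' by Benjamini-Hochberg correction across terms. Term sets are intersected
#' with the universe first; the query must be a subset of the universe.
#'
#' @param query character vector of genes (non-empty, within `universe`).
#' @param terms named list: term -> character vector of genes.
#' @param universe character vector, the gene universe (non-empty).
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param on_adjusted flag on BH-adjusted q (`TRUE`, default) or on raw p.
#' @return data.frame(term, k, K, n, N, p, q, significant) sorted by p.
#' @export
hypergeom_enrich <- function(query, terms, universe, alpha = 0.05,
                             on_adjusted = TRUE) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query genes outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    ts <- intersect(unique(terms[[tm]]), universe)
    K <- length(ts)
    k <- length(intersect(ts, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(pmax(out$p, .Machine$double.xmin))
  out$significant <- if (on_adjusted) out$q < alpha else out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic step-up FDR q-values: with `p` sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq.int(n, 1) * p[o]))[ro]
}

#' Translate a gene set through an ortholog map
#'
#' Maps genes of one species to another using a pair table (one2one and
#' one2many relations both contribute), e.g. to express a query on human
#' orthologs before enrichment.
#'
#' @param genes character vector in the source species.
#' @param map data.frame with `species_a`, `gene_a`, `species_b`, `gene_b`;
#'   direction is detected from the `from`/`to` labels.
#' @param from,to species labels.
#' @return Character vector of unique mapped genes.
#' @export
map_orthologs <- function(genes, map, from, to) {
  fwd <- map[map$species_a == from & map$species_b == to, c("gene_a", "gene_b")]
  rev <- map[map$species_b == from & map$species_a == to, c("gene_b", "gene_a")]
  names(rev) <- c("gene_a", "gene_b")
  pairs <- rbind(fwd, rev)
  unique(pairs$gene_b[pairs$gene_a %in% genes])
}
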