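#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's global
#' random state afterwards, so seeded operations never perturb each other.
#' All randomized functions in this package funnel their `seed` argument
#' through here; none touch global random state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round to nearest integer, halves away from zero (0.5 -> 1, -0.5 -> -1);
# fixed policy for the integer background subtraction
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stderr logging, silenced unless options(scMetamorph.verbose = TRUE)
log_msg <- function(...) {
  if (isTRUE(getOption("scMetamorph.verbose", FALSE)))
    message("[scMetamorph] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stream of distinct 32-bit-safe seeds from one user seed
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}
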