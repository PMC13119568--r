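#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library code never clobbers a user's random
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-participant (or per-stage) seed derived from a master
# seed; kept below .Machine$integer.max so set.seed() accepts it.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

assert_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop(sprintf("`%s` must be a numeric vector of length >= %d", name, min_len),
         call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("`%s` contains missing values", name), call. = FALSE)
  }
  invisible(x)
}
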