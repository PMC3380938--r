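# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the R random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so that seeded helpers do not perturb an
#' enclosing simulation.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## stopifnot() with a readable message
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))

## derive a stream of sub-seeds from one root seed, staying well below 2^31
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(2^31 - 2, n))
}
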