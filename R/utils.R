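## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily-seeded RNG
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the state, so seeded pipeline stages do not perturb each other.
#'
#' @param seed integer seed; `NULL` leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## derive a stream of sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

## canonical unordered pair keys "a|b" with a < b lexicographically
pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "|")
}

## nearest-rank (inverse-ECDF) quantile: smallest x with ECDF(x) >= p
nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}
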