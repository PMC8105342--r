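#' @useDynLib intelligible, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm predict rbinom rnorm qnorm sd quantile
#' @importFrom utils read.csv write.csv head
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library functions do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive independent sub-seeds from one master seed
#'
#' Fans a master seed out to named component seeds (split, bootstrap, model,
#' simulation, ...) so that each pipeline component is reproducible in
#' isolation. Seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_classed <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "intelligible_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) stop_classed(class, fmt, ...)
  invisible(TRUE)
}
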