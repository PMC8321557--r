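#' @importFrom stats rnorm dnorm runif sd var pt quantile
#' @importFrom methods new validObject is slot slotNames
#' @importFrom Rcpp evalCpp
#' @useDynLib epinfer, .registration = TRUE
NULL

## Numerically safe elementwise helpers used across the flow and the models.

sigmoid <- function(x) 1 / (1 + exp(-x))

## log(sigmoid(x)) without overflow for large |x|
logSigmoid <- function(x) ifelse(x < 0, x - log1p(exp(x)), -log1p(exp(-x)))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## inverse of softplus; argument must be positive
softplusInv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-300))))

relu <- function(x) pmax(x, 0)

logit <- function(p) log(p) - log1p(-p)

#' Derive a child RNG seed deterministically from a parent seed
#'
#' Every stochastic operation in the package takes an explicit integer seed.
#' Operations needing several independent streams derive child seeds with this
#' helper, keeping all seeds in the 32-bit integer range.
#'
#' @param seed parent integer seed
#' @param k stream index (non-negative integer)
#' @return an integer seed in \code{[1, 2^31 - 2]}
#' @export
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * (as.numeric(k) + 1)) %%
               2147483646) + 1L
}

## Run an expression under a seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## standard-normal log density of the rows of a matrix
rowLogDnorm <- function(Z) {
  -0.5 * ncol(Z) * log(2 * pi) - 0.5 * rowSums(Z^2)
}

## matrix of iid standard normals under a seed
seededNormals <- function(n, d, seed) {
  withSeed(seed, matrix(rnorm(n * d), nrow = n, ncol = d))
}

stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
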