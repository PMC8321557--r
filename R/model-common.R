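## Shared infrastructure for the circuit-model zoo.

#' Construct a circuit model by name
#'
#' @param name one of \code{"identity"}, \code{"lds2d"}, \code{"rnn"},
#'   \code{"stg"}, \code{"v1"}, \code{"sc"}
#' @param ... arguments passed to the model constructor
#' @return a \linkS4class{CircuitModel}
#' @export
circuitModel <- function(name, ...) {
  switch(name,
    identity = identityModel(...),
    lds2d = lds2dModel(...),
    rnn = rank2RNNModel(...),
    stg = stgModel(...),
    v1 = v1Model(...),
    sc = scModel(...),
    stop("unknown circuit model '", name, "'; registered models: ",
         "identity, lds2d, rnn, stg, v1, sc", call. = FALSE))
}

setMethod("defaultInit", "CircuitModel", function(model) {
  sup <- supportBox(model)
  lo <- sup@lower; up <- sup@upper
  list(mu = ifelse(is.finite(lo) & is.finite(up), (lo + up) / 2, 0),
       sd = ifelse(is.finite(lo) & is.finite(up), (up - lo) / 8, 1))
})

setMethod("show", "CircuitModel", function(object) {
  cat(class(object), "circuit model '", object@name, "': D =",
      paramDim(object), "\n")
  cat("  parameters:", paste(paramNames(object), collapse = ", "), "\n")
  sup <- supportBox(object)
  cat("  support: [", paste(sprintf("%g..%g", sup@lower, sup@upper),
                            collapse = "] x ["), "]\n")
})

## Central finite-difference gradient of trial-averaged statistics with
## common random numbers: statFun(z, seed) must be deterministic in (z, seed)
## so FD along z is the pathwise derivative through reparameterized noise.
## z: n x D; statFun returns an n x mf matrix for an n x D input.
fdStatGrad <- function(statFun, z, seed, h) {
  n <- nrow(z); D <- ncol(z)
  f0 <- statFun(z, seed)
  mf <- ncol(f0)
  G <- array(NA_real_, dim = c(n, mf, D))
  for (j in seq_len(D)) {
    zp <- z; zp[, j] <- zp[, j] + h[j]
    zm <- z; zm[, j] <- zm[, j] - h[j]
    G[, , j] <- (statFun(zp, seed) - statFun(zm, seed)) / (2 * h[j])
  }
  list(f = f0, grad = G)
}

## ---------------------------------------------------------- identity model

#' @rdname circuitModel
#' @param dim dimensionality of the identity model
#' @export
identityModel <- function(dim = 2L) new("IdentityModel", dim = as.integer(dim))

setMethod("paramDim", "IdentityModel", function(model) model@dim)
setMethod("paramNames", "IdentityModel",
          function(model) paste0("z", seq_len(model@dim)))
setMethod("supportBox", "IdentityModel", function(model)
  boxSupport(rep(-Inf, model@dim), rep(Inf, model@dim)))
setMethod("simulateCircuit", "IdentityModel",
          function(model, z, seed, ...) matrix(z, nrow = 1L))
setMethod("circuitStatistics", "IdentityModel",
  function(model, z, nTrials = 1L, seed = 1L, withGrad = FALSE) {
    n <- nrow(z); D <- ncol(z)
    grad <- NULL
    if (withGrad) {
      grad <- array(0, dim = c(n, D, D))
      for (k in seq_len(D)) grad[, k, k] <- 1
    }
    list(f = z, grad = grad)
  })
setMethod("defaultHyperparams", "IdentityModel", function(model)
  alHyperparams(c0 = 1, beta = 2, imax = 300L, kmax = 6L, batchN = 200L,
                Ntest = 100L, testReps = 200L))
setMethod("defaultArchitecture", "IdentityModel", function(model)
  flowArchitecture(nCouplingStages = 3L, conditionerDepth = 2L,
                   conditionerWidth = 30L, dim = model@dim))
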