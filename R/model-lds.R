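## Two-dimensional linear dynamical system tau*dx/dt = A x. The emergent
## property lives on the primary eigenvalue of A, available in closed form
## from the characteristic polynomial, so statistics and their parameter
## gradients are analytic.

#' @rdname circuitModel
#' @param tau LDS time constant in seconds
#' @export
lds2dModel <- function(tau = 1) new("LDS2D", tau = tau)

setMethod("paramDim", "LDS2D", function(model) 4L)
setMethod("paramNames", "LDS2D",
          function(model) c("a11", "a12", "a21", "a22"))
setMethod("supportBox", "LDS2D",
          function(model) boxSupport(rep(-10, 4), rep(10, 4)))

#' Primary eigenvalue of the 2-D LDS in closed form
#'
#' Quadratic-formula eigenvalues of A/tau. The primary eigenvalue lambda1 is
#' the one of greatest real part when both are real, and the member of the
#' conjugate pair with positive imaginary part otherwise.
#'
#' @param z length-4 vector or n x 4 matrix (a11, a12, a21, a22)
#' @param tau time constant in seconds
#' @return n x 2 matrix with columns real(lambda1), imag(lambda1)
#' @export
lds2dStatistics <- function(z, tau = 1) {
  z <- asPointMatrix(z, 4L)
  tr <- (z[, 1] + z[, 4]) / tau
  dt <- (z[, 1] * z[, 4] - z[, 2] * z[, 3]) / tau^2
  disc <- tr^2 - 4 * dt
  re <- ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
  im <- ifelse(disc >= 0, 0, sqrt(pmax(-disc, 0)) / 2)
  cbind(re, im, deparse.level = 0)
}

lds2dStatGrad <- function(z, tau = 1) {
  n <- nrow(z)
  tr <- (z[, 1] + z[, 4]) / tau
  dt <- (z[, 1] * z[, 4] - z[, 2] * z[, 3]) / tau^2
  disc <- tr^2 - 4 * dt
  ## d tr / dz and d det / dz
  dTr <- cbind(1, 0, 0, 1) / tau
  dDt <- cbind(z[, 4], -z[, 3], -z[, 2], z[, 1]) / tau^2
  G <- array(0, dim = c(n, 2L, 4L))
  real <- disc >= 0
  sq <- sqrt(abs(disc))
  for (j in 1:4) {
    dTrj <- rep(dTr[j], n)
    dDiscj <- 2 * tr * dTrj - 4 * dDt[, j]
    ## real branch: re = (tr + sqrt(disc))/2, im = 0
    G[, 1, j] <- ifelse(real,
                        (dTrj + dDiscj / (2 * pmax(sq, 1e-12))) / 2,
                        dTrj / 2)
    ## complex branch: im = sqrt(-disc)/2
    G[, 2, j] <- ifelse(real, 0, -dDiscj / (4 * pmax(sq, 1e-12)))
  }
  G
}

setMethod("circuitStatistics", "LDS2D",
  function(model, z, nTrials = 1L, seed = 1L, withGrad = FALSE) {
    f <- lds2dStatistics(z, model@tau)
    colnames(f) <- c("real_lambda1", "imag_lambda1")
    list(f = f, grad = if (withGrad) lds2dStatGrad(as.matrix(z), model@tau)
                       else NULL)
  })

setMethod("simulateCircuit", "LDS2D",
  function(model, z, seed, x0 = c(1, 0), tMax = 4, dt = 0.01, ...) {
    A <- matrix(z, 2L, 2L, byrow = TRUE)
    nT <- ceiling(tMax / dt)
    X <- matrix(NA_real_, 2L, nT)
    x <- x0
    for (t in seq_len(nT)) {
      x <- x + dt / model@tau * as.numeric(A %*% x)
      X[, t] <- x
    }
    X
  })

#' The oscillating-linear-system emergent property
#'
#' real(lambda1) with mean 0 and variance 0.25^2; imag(lambda1) with mean
#' 2*pi (1 Hz oscillation) and variance (pi/5)^2.
#' @return an \linkS4class{EmergentProperty}
#' @export
lds2dOscillationProperty <- function() {
  emergentProperty(c("real_lambda1", "imag_lambda1"),
                   mu = c(0, 2 * pi), sigma2 = c(0.25^2, (pi / 5)^2),
                   innerTrials = 1L)
}

## wide initialization: the oscillation band lives at |a12|, |a21| ~ 2*pi
setMethod("defaultInit", "LDS2D", function(model)
  list(mu = rep(0, 4), sd = rep(4, 4)))

setMethod("defaultHyperparams", "LDS2D", function(model)
  alHyperparams(c0 = 10, beta = 2, imax = 1000L, kmax = 10L, batchN = 200L,
                Ntest = 100L, testReps = 200L))
setMethod("defaultArchitecture", "LDS2D", function(model)
  flowArchitecture(nCouplingStages = 3L, conditionerDepth = 2L,
                   conditionerWidth = 50L, dim = 4L))
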