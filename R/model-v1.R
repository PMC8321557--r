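## Four-population stochastic stabilized supralinear network (SSSN) of V1:
## excitatory (E), parvalbumin (P), somatostatin (S) and VIP (V) populations
## with supralinear transfer phi(v) = relu(v)^2 and slow Ornstein-Uhlenbeck
## input noise. Free parameters z = (sigma_E, sigma_P, sigma_S, sigma_V).
## Units: Hz and ms.

.v1W <- matrix(c(
   0.218, -0.119,  -0.0594,  -0.0229,
   0.166, -0.0651, -0.068,   -0.0242,
   0.0895, -5.22e-4, -1.51e-5, -0.0761,
   0.334, -0.231,  -0.0254,  -2.52e-5), 4L, 4L, byrow = TRUE,
  dimnames = list(c("E", "P", "S", "V"), c("E", "P", "S", "V")))

#' @rdname circuitModel
#' @param contrast stimulus contrast in [0, 1]
#' @export
v1Model <- function(contrast = 1) {
  new("V1SSN", name = "v1", W = .v1W,
      hb = c(4.16, 4.29, 4.91, 4.86), hc = c(3.59, 4.03, 0, 0),
      contrast = contrast, tau = 1, tauNoise = 5, dt = 0.5, nSteps = 200L)
}

setMethod("paramDim", "V1SSN", function(model) 4L)
setMethod("paramNames", "V1SSN",
          function(model) c("sigma_E", "sigma_P", "sigma_S", "sigma_V"))
setMethod("supportBox", "V1SSN",
          function(model) boxSupport(rep(0, 4), rep(0.5, 4)))

v1Input <- function(model) model@hb + model@contrast * model@hc

## Batched joint Euler-Maruyama of rates and OU noise. Rows of zMat are
## parameter draws; each is simulated `trials` times with common
## reparameterized noise across zMat perturbations (same seed => same
## increments). Returns the E-rate trace (B*trials x T) unless fullTrace.
v1SimulateBatch <- function(model, zMat, trials, seed, fullTrace = FALSE) {
  B <- nrow(zMat); n <- B * trials
  sigma <- zMat[rep(seq_len(B), each = trials), , drop = FALSE]
  sigTil <- sigma * sqrt(1 + model@tau / model@tauNoise)
  h <- v1Input(model)
  x <- withSeed(childSeed(seed, 1L), matrix(runif(n * 4, 10, 25), n, 4))
  eps0 <- withSeed(childSeed(seed, 2L), matrix(rnorm(n * 4), n, 4))
  eps <- eps0 * sigTil                     # stationary OU start
  noise <- withSeed(childSeed(seed, 3L),
                    array(rnorm(n * 4 * model@nSteps),
                          dim = c(n, 4, model@nSteps)))
  ouScale <- sqrt(2 * model@dt / model@tauNoise)
  Wt <- t(model@W)
  xE <- matrix(NA_real_, n, model@nSteps)
  full <- if (fullTrace) array(NA_real_, dim = c(n, 4, model@nSteps)) else NULL
  for (t in seq_len(model@nSteps)) {
    v <- x %*% Wt + matrix(h, n, 4, byrow = TRUE) + eps
    x <- x + model@dt / model@tau * (-x + relu(v)^2)
    eps <- eps - model@dt / model@tauNoise * eps +
      ouScale * sigTil * noise[, , t]
    bad <- rowSums(!is.finite(x) | x > 1e5) > 0L
    if (any(bad)) x[bad, ] <- NaN   # supralinear runaway: abort these trials
    xE[, t] <- x[, 1]
    if (fullTrace) full[, , t] <- x
  }
  list(xE = xE, full = full, blown = !is.finite(xE[, ncol(xE)]))
}

#' Simulate the V1 SSSN at one parameter value
#'
#' @param model a \linkS4class{V1SSN} (defaults to \code{v1Model()})
#' @param z noise scales c(sigma_E, sigma_P, sigma_S, sigma_V)
#' @param trials independent trials
#' @param seed integer seed
#' @return trials x 4 x T array of population rates (Hz). Trials whose rates
#'   exceed 1e5 Hz (supralinear runaway) are aborted: their rates are NaN
#'   from the blow-up step onward and flagged in the \code{"blown"}
#'   attribute.
#' @export
v1Simulate <- function(z, trials = 1L, seed = 1L, model = v1Model()) {
  sim <- v1SimulateBatch(model, matrix(z, 1L, 4L), trials, seed,
                         fullTrace = TRUE)
  structure(sim$full, blown = sim$blown)
}

setMethod("simulateCircuit", "V1SSN",
  function(model, z, seed, nTrials = 1L, ...)
    v1Simulate(z, trials = nTrials, seed = seed, model = model))

#' Standard deviation of the E-population rate about its steady state
#'
#' Temporal standard deviation of the E rate over t in (75 ms, 100 ms].
#'
#' @param xE numeric vector or B x T matrix of E rates (Hz)
#' @param dt sample interval (ms)
#' @param tss steady-state onset (ms)
#' @param tEnd window end (ms)
#' @return numeric vector of s_E values (Hz)
#' @export
v1sE <- function(xE, dt = 0.5, tss = 75, tEnd = 100) {
  X <- if (is.null(dim(xE))) matrix(xE, 1L) else as.matrix(xE)
  idx <- which(seq_len(ncol(X)) * dt > tss & seq_len(ncol(X)) * dt <= tEnd)
  if (length(idx) < 2L) stop("trace must cover at least 100 ms", call. = FALSE)
  Xw <- X[, idx, drop = FALSE]
  sqrt(rowMeans((Xw - rowMeans(Xw))^2))
}

setMethod("circuitStatistics", "V1SSN",
  function(model, z, nTrials = 100L, seed = 1L, withGrad = FALSE) {
    z <- asPointMatrix(z, 4L)
    statFun <- function(zz, sd_) {
      sim <- v1SimulateBatch(model, zz, nTrials, sd_)
      se <- v1sE(sim$xE, dt = model@dt)
      grp <- rep(seq_len(nrow(zz)), each = nTrials)
      matrix(as.numeric(tapply(se, grp, mean)), ncol = 1L,
             dimnames = list(NULL, "sE"))
    }
    if (!withGrad) return(list(f = statFun(z, seed), grad = NULL))
    fdStatGrad(statFun, z, seed, h = rep(0.004, 4L))
  })

#' Deterministic steady state of the V1 circuit
#'
#' Integrates the noiseless dynamics to the fixed point
#' \code{x* = phi(W x* + h)}.
#'
#' @param model a \linkS4class{V1SSN}
#' @param h input vector (default: the model's contrast input)
#' @param x0 initial rates
#' @param tol fixed-point residual tolerance (Hz)
#' @param maxSteps iteration cap
#' @return steady-state rate vector (Hz)
#' @export
v1SteadyState <- function(model = v1Model(), h = v1Input(model),
                          x0 = rep(15, 4), tol = 1e-9, maxSteps = 200000L) {
  x <- x0
  for (i in seq_len(maxSteps)) {
    xn <- x + model@dt / model@tau *
      (-x + relu(as.numeric(model@W %*% x) + h)^2)
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  warning("v1SteadyState: fixed point not reached to tol")
  x
}

#' Lyapunov oracle for input-fluctuation covariance (white-noise limit)
#'
#' In the tau_noise = tau limit the linearized input fluctuations delta-v
#' obey \code{tau d(dv) = -S dv dt + sqrt(2 tau) diag(sigmaTilde) dW} with
#' \code{S = I - W phi'(v*)}; their stationary covariance solves the
#' Lyapunov equation \code{S L + L S' = 2 diag(sigmaTilde^2)}.
#'
#' @param model a \linkS4class{V1SSN}
#' @param z noise scales (sigma)
#' @param xStar steady state (default: computed)
#' @return 4 x 4 covariance matrix
#' @export
v1LyapunovOracle <- function(model = v1Model(), z, xStar = NULL) {
  if (is.null(xStar)) xStar <- v1SteadyState(model)
  h <- v1Input(model)
  vStar <- as.numeric(model@W %*% xStar) + h
  S <- diag(4) - model@W %*% diag(2 * relu(vStar))
  if (any(Re(eigen(S, only.values = TRUE)$values) <= 0))
    stop("v1LyapunovOracle: unstable linearization", call. = FALSE)
  sigTil <- as.numeric(z) * sqrt(1 + model@tau / model@tauNoise)
  Q <- 2 * diag(sigTil^2)
  ## vectorized solve of S L + L S' = Q
  K <- kronecker(diag(4), S) + kronecker(S, diag(4))
  matrix(solve(K, as.numeric(Q)), 4L, 4L)
}

#' Test a population for the paradoxical effect
#'
#' Adds a small constant input to one population and compares the new steady
#' state to baseline: the effect is paradoxical when the stimulated
#' population's rate moves opposite to its input change.
#'
#' @param population one of "E", "P", "S", "V"
#' @param deltaH input perturbation (0.002 for E/P, 0.02 for S/V makes the
#'   effect salient)
#' @param model a \linkS4class{V1SSN}
#' @return list with \code{paradoxical}, \code{rateChange}, \code{baseline}
#' @export
v1ParadoxicalTest <- function(population, deltaH = NULL, model = v1Model()) {
  ip <- match(population, c("E", "P", "S", "V"))
  if (is.na(ip)) stop("unknown population", call. = FALSE)
  if (is.null(deltaH)) deltaH <- if (ip <= 2L) 0.002 else 0.02
  h0 <- v1Input(model)
  x0 <- v1SteadyState(model, h0)
  h1 <- h0; h1[ip] <- h1[ip] + deltaH
  x1 <- v1SteadyState(model, h1, x0 = x0)
  dRate <- x1[ip] - x0[ip]
  list(paradoxical = sign(dRate) == -sign(deltaH), rateChange = dRate,
       baseline = x0)
}

#' The E-population variability emergent property
#'
#' s_E with mean \code{level} Hz (5 or 10 in practice) and variance 1 Hz^2,
#' averaged over \code{innerTrials} simulations per parameter draw.
#' @param level target mean of s_E in Hz
#' @param innerTrials simulations averaged per draw
#' @return an \linkS4class{EmergentProperty}
#' @export
v1VariabilityProperty <- function(level = 5, innerTrials = 100L) {
  emergentProperty("sE", mu = level, sigma2 = 1, innerTrials = innerTrials)
}

## initialization inside the noise-stable band: small sigma_E/sigma_P
setMethod("defaultInit", "V1SSN", function(model)
  list(mu = c(0.02, 0.02, 0.15, 0.15), sd = c(0.01, 0.01, 0.05, 0.05)))

setMethod("defaultHyperparams", "V1SSN", function(model)
  alHyperparams(c0 = 0.1, beta = 2, imax = 2000L, kmax = 10L, batchN = 100L,
                Ntest = 100L, testReps = 200L))
setMethod("defaultArchitecture", "V1SSN", function(model)
  flowArchitecture(nCouplingStages = 3L, conditionerDepth = 2L,
                   conditionerWidth = 50L, dim = 4L))
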