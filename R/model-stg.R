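## Five-neuron stomatogastric-ganglion subcircuit: two mutually inhibiting
## fast cells (pyloric), two mutually inhibiting slow cells (gastric mill)
## and a hub neuron electrically coupled to one cell of each pair and
## synaptically inhibited by the other. Morris-Lecar-style conductance
## dynamics with calcium (instantaneous), potassium (gated N) and
## hyperpolarization (gated H) currents; 15-dimensional state.
##
## Units: mV, ms, uS, nF, nA. Free parameters z = (g_el, g_synA) in nS.

.stgConst <- list(
  Cm = 1,                       # nF
  gLeak = 1e-4,                 # uS
  ## per-neuron-type conductances (uS): order f1, f2, hub, s1, s2
  gCa = c(1.9e-2, 1.9e-2, 1.7e-2, 8.5e-3, 8.5e-3),
  gK  = c(3.9e-2, 3.9e-2, 1.9e-2, 1.5e-2, 1.5e-2),
  gH  = c(2.5e-2, 2.5e-2, 8.0e-3, 1.0e-2, 1.0e-2),
  VLeak = -40, VCa = 100, VK = -80, VHyp = -20, VSyn = -75,  # mV
  v1 = 0, v2 = 20, v3 = 0, v4 = 15, v5 = 78.3, v6 = 10.5,
  v7 = -42.2, v8 = 87.3, v9 = 5, vth = -25,
  phiN = 0.002,                 # 1/ms, Morris-Lecar rate constant
  gSynB = 5e-3)                 # uS (5 nS), mutual inhibition

## Fixed initial membrane potentials (mV), staggered within each half-center
## pair to break the inhibitory symmetry; gates start at steady state. A
## deterministic start keeps the within-parameter frequency variability at
## the scale of the current noise, as the tight variance target requires.
.stgX0 <- c(-65, -40, -55, -65, -40)

#' @rdname circuitModel
#' @param dt STG integration step in ms
#' @param nSteps STG samples per trace
#' @export
stgModel <- function(dt = 25, nSteps = 300L) {
  new("STGCircuit", dt = dt, nSteps = as.integer(nSteps), noiseSd = 1e-3)
}

setMethod("paramDim", "STGCircuit", function(model) 2L)
setMethod("paramNames", "STGCircuit", function(model) c("g_el", "g_synA"))
setMethod("supportBox", "STGCircuit",
          function(model) boxSupport(c(4, 0.01), c(8, 4)))

stgGates <- function(x, cc = .stgConst) {
  list(Minf = 0.5 * (1 + tanh((x - cc$v1) / cc$v2)),
       Ninf = 0.5 * (1 + tanh((x - cc$v3) / cc$v4)),
       lamN = cc$phiN * cosh((x - cc$v3) / (2 * cc$v4)),
       Hinf = 1 / (1 + exp((x + cc$v5) / cc$v6)),
       tauH = 272 + 1499 / (1 + exp((-x + cc$v7) / cc$v8)),
       Sinf = 1 / (1 + exp((cc$vth - x) / cc$v9)))
}

## Batched Euler-Maruyama on B parameter rows at once. State matrices are
## B x 5 (columns f1, f2, hub, s1, s2). Noise is reparameterized: the same
## seed yields the same increments for any z, so finite differences along z
## are pathwise derivatives. Returns hub trace (B x T) and optionally the
## full voltage array (B x 5 x T). The integration loop runs in compiled
## code; stgSimulateBatchR is the plain-R reference used to validate it.
stgSimulateBatch <- function(zMat, nSteps, dt, seed, noiseSd = 1e-3,
                             fullTrace = FALSE) {
  B <- nrow(zMat)
  x0 <- matrix(.stgX0, B, 5, byrow = TRUE)
  noise <- withSeed(childSeed(seed, 2L),
                    array(rnorm(B * 5 * nSteps), dim = c(B, 5, nSteps)))
  out <- .stgSimulateCpp(zMat, as.integer(nSteps), dt, x0,
                         as.numeric(noise), noiseSd, fullTrace)
  if (fullTrace) out$full <- array(out$full, dim = c(B, 5L, nSteps))
  out
}

stgSimulateBatchR <- function(zMat, nSteps, dt, seed, noiseSd = 1e-3,
                              fullTrace = FALSE) {
  cc <- .stgConst
  B <- nrow(zMat)
  gel <- zMat[, 1] * 1e-3       # nS -> uS
  gsA <- zMat[, 2] * 1e-3
  x0 <- matrix(.stgX0, B, 5, byrow = TRUE)
  g0 <- stgGates(x0)
  x <- x0; N <- g0$Ninf; H <- g0$Hinf
  noise <- withSeed(childSeed(seed, 2L),
                    array(rnorm(B * 5 * nSteps), dim = c(B, 5, nSteps)))
  hub <- matrix(NA_real_, B, nSteps)
  full <- if (fullTrace) array(NA_real_, dim = c(B, 5, nSteps)) else NULL
  gCa <- matrix(cc$gCa, B, 5, byrow = TRUE)
  gK <- matrix(cc$gK, B, 5, byrow = TRUE)
  gH <- matrix(cc$gH, B, 5, byrow = TRUE)
  sqdt <- sqrt(dt)
  for (t in seq_len(nSteps)) {
    gt <- stgGates(x)
    I <- cc$gLeak * (x - cc$VLeak) +
      gCa * gt$Minf * (x - cc$VCa) +
      gK * N * (x - cc$VK) +
      gH * H * (x - cc$VHyp)
    ## electrical coupling: f1<->hub and s1<->hub
    I[, 1] <- I[, 1] + gel * (x[, 1] - x[, 3])
    I[, 4] <- I[, 4] + gel * (x[, 4] - x[, 3])
    I[, 3] <- I[, 3] + gel * (x[, 3] - x[, 1]) + gel * (x[, 3] - x[, 4])
    ## synaptic inhibition: mutual within pairs (gSynB), f2/s2 -> hub (gsA)
    I[, 1] <- I[, 1] + cc$gSynB * gt$Sinf[, 2] * (x[, 1] - cc$VSyn)
    I[, 2] <- I[, 2] + cc$gSynB * gt$Sinf[, 1] * (x[, 2] - cc$VSyn)
    I[, 4] <- I[, 4] + cc$gSynB * gt$Sinf[, 5] * (x[, 4] - cc$VSyn)
    I[, 5] <- I[, 5] + cc$gSynB * gt$Sinf[, 4] * (x[, 5] - cc$VSyn)
    I[, 3] <- I[, 3] + gsA * gt$Sinf[, 2] * (x[, 3] - cc$VSyn) +
      gsA * gt$Sinf[, 5] * (x[, 3] - cc$VSyn)
    x <- x + dt * (-I / cc$Cm) + sqdt * noiseSd / cc$Cm * noise[, , t]
    N <- N + dt * gt$lamN * (gt$Ninf - N)
    H <- H + dt * (gt$Hinf - H) / gt$tauH
    if (any(!is.finite(x)))
      stop("stgSimulateBatch: non-finite state at step ", t, call. = FALSE)
    hub[, t] <- x[, 3]
    if (fullTrace) full[, , t] <- x
  }
  list(hub = hub, full = full)
}

#' Simulate the STG subcircuit at one parameter value
#'
#' @param z c(g_el, g_synA) in nS
#' @param seed integer seed (initial conditions and current noise)
#' @param nSteps,dt override the model's trace length / step (ms)
#' @param noiseSd current noise scale (nA)
#' @return 5 x T matrix of membrane potentials (mV), rows f1, f2, hub, s1, s2
#' @export
stgSimulate <- function(z, seed = 1L, nSteps = 300L, dt = 25,
                        noiseSd = 1e-3) {
  sim <- stgSimulateBatch(matrix(z, 1L, 2L), nSteps, dt, seed, noiseSd,
                          fullTrace = TRUE)
  tr <- matrix(sim$full[1L, , ], 5L, nSteps)
  rownames(tr) <- c("f1", "f2", "hub", "s1", "s2")
  tr
}

setMethod("simulateCircuit", "STGCircuit",
  function(model, z, seed, ...)
    stgSimulate(z, seed, model@nSteps, model@dt, model@noiseSd))

#' Differentiable spiking-frequency readout of a voltage trace
#'
#' Drops the first 20 samples (initial transients), rectifies about 0 mV
#' (spike extraction), low-pass filters with a 20-sample moving average,
#' centers the result, projects it onto a bank of complex exponentials with
#' frequencies 0.00 to 1.00 Hz at 0.01 Hz resolution, and returns the
#' soft-argmax (temperature 100) frequency-index expectation in Hz. An
#' all-zero processed trace is degenerate and returns 0 Hz.
#'
#' @param trace numeric vector (one voltage trace, mV) or B x T matrix
#' @param dt sample interval in ms
#' @param betaPsi soft-argmax temperature
#' @param burnIn samples discarded at the start
#' @param maWindow moving-average window length
#' @return list with \code{freq} (Hz, length B) and \code{degenerate}
#'   (logical flags)
#' @export
stgHubFrequency <- function(trace, dt = 25, betaPsi = 100, burnIn = 20L,
                            maWindow = 20L) {
  X <- if (is.null(dim(trace))) matrix(trace, 1L) else as.matrix(trace)
  if (ncol(X) < burnIn + maWindow)
    stop("trace too short for burn-in plus filter window", call. = FALSE)
  X <- X[, -(seq_len(burnIn)), drop = FALSE]
  X <- relu(X)
  ## moving average, valid positions only, via cumulative sums
  cs <- t(apply(cbind(0, X), 1L, cumsum))
  M <- (cs[, (maWindow + 1L):ncol(cs), drop = FALSE] -
          cs[, seq_len(ncol(cs) - maWindow), drop = FALSE]) / maWindow
  M <- M - rowMeans(M)
  nT <- ncol(M)
  tSec <- (seq_len(nT) - 1L) * dt / 1000
  freqs <- seq(0, 1, by = 0.01)
  ER <- cos(2 * pi * outer(tSec, freqs))
  EI <- sin(2 * pi * outer(tSec, freqs))
  mag <- sqrt((M %*% ER)^2 + (M %*% EI)^2)
  degenerate <- apply(mag, 1L, max) < 1e-9
  W <- exp(betaPsi * (mag - apply(mag, 1L, max)))
  W <- W / rowSums(W)
  freq <- as.numeric(W %*% freqs)
  freq[degenerate] <- 0
  list(freq = freq, degenerate = degenerate)
}

setMethod("circuitStatistics", "STGCircuit",
  function(model, z, nTrials = 1L, seed = 1L, withGrad = FALSE) {
    z <- asPointMatrix(z, 2L)
    statFun <- function(zz, sd_) {
      acc <- matrix(0, nrow(zz), nTrials)
      for (tr in seq_len(nTrials)) {
        sim <- stgSimulateBatch(zz, model@nSteps, model@dt,
                                seed = childSeed(sd_, tr),
                                noiseSd = model@noiseSd)
        acc[, tr] <- stgHubFrequency(sim$hub, dt = model@dt)$freq
      }
      matrix(rowMeans(acc), ncol = 1L,
             dimnames = list(NULL, "hubFrequency"))
    }
    if (!withGrad) return(list(f = statFun(z, seed), grad = NULL))
    fdStatGrad(statFun, z, seed, h = c(0.04, 0.02))
  })

#' The intermediate-hub-frequency emergent property
#'
#' Hub neuron frequency with mean 0.55 Hz and variance 0.025^2 Hz^2, between
#' the intrinsic frequencies of the fast and slow half-centers.
#' @return an \linkS4class{EmergentProperty}
#' @export
stgHubProperty <- function() {
  emergentProperty("hubFrequency", mu = 0.55, sigma2 = 0.025^2,
                   innerTrials = 1L)
}

setMethod("defaultHyperparams", "STGCircuit", function(model)
  alHyperparams(c0 = 1e5, beta = 2, imax = 5000L, kmax = 10L, batchN = 400L,
                Ntest = 100L, testReps = 200L))
setMethod("defaultArchitecture", "STGCircuit", function(model)
  flowArchitecture(nCouplingStages = 3L, conditionerDepth = 2L,
                   conditionerWidth = 25L, dim = 2L))
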