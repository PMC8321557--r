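## Superior-colliculus task-switching network: four populations (left/right
## Pro and Anti) with hemisphere-symmetric connectivity parameterized by
## z = (sW, vW, hW, dW) and a structured trial-input sequence. Responses are
## bounded in (0, 1) by a shifted tanh; decisions are read out at trial end
## through a sharp sigmoid. Units: seconds.

#' @rdname circuitModel
#' @export
scModel <- function() {
  new("SCNetwork", name = "sc", tau = 0.09, dt = 0.024, trialLength = 1.8,
      noiseSd = 0.2,
      inputs = c(constant = 0.75, Pbias = 0.5, Prule = 0.6, Arule = 0.6,
                 choice = 0.25, light = 0.5),
      betaTheta = 100)
}

setMethod("paramDim", "SCNetwork", function(model) 4L)
setMethod("paramNames", "SCNetwork", function(model) c("sW", "vW", "hW", "dW"))
setMethod("supportBox", "SCNetwork",
          function(model) boxSupport(rep(-5, 4), rep(5, 4)))

## population order everywhere: LP, LA, RP, RA
scNonlin <- function(u, a = 0.05, b = 0.5) 0.5 * tanh((u - a) / b) + 0.5

#' Connectivity matrix of the SC model
#' @param z c(sW, vW, hW, dW)
#' @return 4 x 4 matrix over populations (LP, LA, RP, RA)
#' @export
scConnectivity <- function(z) {
  s <- z[1]; v <- z[2]; h <- z[3]; d <- z[4]
  matrix(c(s, v, h, d,
           v, s, d, h,
           h, d, s, v,
           d, h, v, s), 4L, 4L, byrow = TRUE,
         dimnames = list(c("LP", "LA", "RP", "RA"),
                         c("LP", "LA", "RP", "RA")))
}

#' Trial input to the SC circuit at time t
#'
#' Sum of the constant drive, the Pro-population bias, the cue-period rule
#' input (t <= 1.2 s), the choice-period input (t > 1.2 s) and the
#' side-specific light input (1.2 s < t < 1.5 s).
#'
#' @param t time within the trial, 0 <= t <= 1.8 (s)
#' @param task "Pro" or "Anti"
#' @param side "Left" or "Right" (stimulated side)
#' @param model a \linkS4class{SCNetwork}
#' @return input 4-vector over (LP, LA, RP, RA)
#' @export
scInput <- function(t, task = c("Pro", "Anti"), side = c("Left", "Right"),
                    model = scModel()) {
  task <- match.arg(task); side <- match.arg(side)
  if (t < 0 || t > model@trialLength)
    stop("scInput: t outside the trial [0, ", model@trialLength, "] s",
         call. = FALSE)
  I <- model@inputs
  h <- rep(I[["constant"]], 4L)
  h <- h + I[["Pbias"]] * c(1, 0, 1, 0)
  if (t <= 1.2) {
    h <- h + if (task == "Pro") I[["Prule"]] * c(1, 0, 1, 0)
             else I[["Arule"]] * c(0, 1, 0, 1)
  } else {
    h <- h + I[["choice"]]
  }
  if (t > 1.2 && t < 1.5) {
    h <- h + if (side == "Left") I[["light"]] * c(1, 1, 0, 0)
             else I[["light"]] * c(0, 0, 1, 1)
  }
  names(h) <- c("LP", "LA", "RP", "RA")
  h
}

## Batched trial simulation: rows of zMat x trials, common reparameterized
## noise. Optogenetic silencing scales activity by (1 - gamma) during the
## delay window 0.8 < t < 1.2 s. Returns final activity (n x 4) and
## optionally the full trace.
scSimulateBatch <- function(model, zMat, task, side, gamma, trials, seed,
                            fullTrace = FALSE) {
  B <- nrow(zMat); n <- B * trials
  nSteps <- round(model@trialLength / model@dt)
  zExp <- zMat[rep(seq_len(B), each = trials), , drop = FALSE]
  noise <- withSeed(childSeed(seed, 1L),
                    array(rnorm(n * 4 * nSteps), dim = c(n, 4, nSteps)))
  u <- matrix(0, n, 4)
  x <- scNonlin(u)
  sq <- model@noiseSd * sqrt(model@dt) / model@tau
  full <- if (fullTrace) array(NA_real_, dim = c(n, 4, nSteps)) else NULL
  for (k in seq_len(nSteps)) {
    tNow <- (k - 1L) * model@dt
    h <- scInput(tNow, task, side, model)
    Wx <- cbind(
      zExp[, 1] * x[, 1] + zExp[, 2] * x[, 2] + zExp[, 3] * x[, 3] +
        zExp[, 4] * x[, 4],
      zExp[, 2] * x[, 1] + zExp[, 1] * x[, 2] + zExp[, 4] * x[, 3] +
        zExp[, 3] * x[, 4],
      zExp[, 3] * x[, 1] + zExp[, 4] * x[, 2] + zExp[, 1] * x[, 3] +
        zExp[, 2] * x[, 4],
      zExp[, 4] * x[, 1] + zExp[, 3] * x[, 2] + zExp[, 2] * x[, 3] +
        zExp[, 1] * x[, 4])
    u <- u + model@dt / model@tau *
      (-u + Wx + matrix(h, n, 4, byrow = TRUE)) + sq * noise[, , k]
    tNext <- k * model@dt
    x <- scNonlin(u)
    if (gamma > 0 && tNext > 0.8 && tNext < 1.2) x <- (1 - gamma) * x
    if (fullTrace) full[, , k] <- x
  }
  list(xFinal = x, full = full, nSteps = nSteps)
}

#' Simulate SC trials at one connectivity
#'
#' @param z c(sW, vW, hW, dW)
#' @param task "Pro" or "Anti"; @param side stimulated side
#' @param gamma optogenetic strength in [0, 1] (delay-period silencing)
#' @param trials independent trials
#' @param seed integer seed
#' @param model a \linkS4class{SCNetwork}
#' @return trials x 4 x T array of activities in (0, 1)
#' @export
scSimulate <- function(z, task = "Pro", side = "Left", gamma = 0,
                       trials = 1L, seed = 1L, model = scModel()) {
  stopifnot(gamma >= 0, gamma <= 1)
  sim <- scSimulateBatch(model, matrix(z, 1L, 4L), task, side, gamma,
                         trials, seed, fullTrace = TRUE)
  sim$full
}

setMethod("simulateCircuit", "SCNetwork",
  function(model, z, seed, task = "Pro", side = "Left", gamma = 0,
           nTrials = 1L, ...)
    scSimulate(z, task, side, gamma, nTrials, seed, model))

#' Soft task accuracy from end-of-trial activities
#'
#' For Left-stimulus trials (the model is left-right symmetric): Pro decision
#' d_P = sigmoid(beta * (x_LP - x_RP)), Anti decision
#' d_A = sigmoid(beta * (x_RP - x_LP)), evaluated at t = 1.8 s; accuracy is
#' the trial mean.
#'
#' @param xFinal trials x 4 matrix of end-of-trial activities (LP, LA, RP,
#'   RA), or a trials x 4 x T array (the last time point is used)
#' @param task "Pro" or "Anti"
#' @param betaTheta Heaviside sharpness
#' @return list with \code{accuracy} and \code{decisions} (per trial)
#' @export
scAccuracy <- function(xFinal, task = c("Pro", "Anti"), betaTheta = 100) {
  task <- match.arg(task)
  if (length(dim(xFinal)) == 3L) xFinal <- xFinal[, , dim(xFinal)[3L]]
  if (is.null(dim(xFinal))) xFinal <- matrix(xFinal, 1L)
  dlt <- xFinal[, 1] - xFinal[, 3]               # x_LP - x_RP
  d <- if (task == "Pro") sigmoid(betaTheta * dlt)
       else sigmoid(-betaTheta * dlt)
  list(accuracy = mean(d), decisions = d)
}

setMethod("circuitStatistics", "SCNetwork",
  function(model, z, nTrials = 200L, seed = 1L, withGrad = FALSE) {
    z <- asPointMatrix(z, 4L)
    statFun <- function(zz, sd_) {
      B <- nrow(zz)
      f <- matrix(NA_real_, B, 2L, dimnames = list(NULL, c("pP", "pA")))
      for (tk in 1:2) {
        task <- c("Pro", "Anti")[tk]
        sim <- scSimulateBatch(model, zz, task, "Left", gamma = 0,
                               trials = nTrials, seed = childSeed(sd_, tk))
        dlt <- sim$xFinal[, 1] - sim$xFinal[, 3]
        d <- if (task == "Pro") sigmoid(model@betaTheta * dlt)
             else sigmoid(-model@betaTheta * dlt)
        grp <- rep(seq_len(B), each = nTrials)
        f[, tk] <- as.numeric(tapply(d, grp, mean))
      }
      f
    }
    if (!withGrad) return(list(f = statFun(z, seed), grad = NULL))
    fdStatGrad(statFun, z, seed, h = rep(0.02, 4L))
  })

#' Eigenvalues of the SC connectivity from its parameters
#'
#' The hemisphere-symmetric structure fixes the eigenvectors of W(z); the
#' eigenvalues (all, side, task, diag amplification) are the linear map
#' \code{lambda = A^{-1} z = 4 A' z} of the parameters.
#'
#' @param z c(sW, vW, hW, dW)
#' @return named eigenvalue 4-vector (all, side, task, diag)
#' @export
scConnectivityEigvals <- function(z) {
  lam <- as.numeric(4 * t(scEigModeBasis()) %*% z)
  names(lam) <- c("all", "side", "task", "diag")
  lam
}

## the matrix A with z = A lambda; columns are the eigenmode directions
scEigModeBasis <- function() {
  matrix(c(1,  1,  1,  1,
           1, -1, -1,  1,
           1,  1, -1, -1,
           1, -1,  1, -1) / 4, 4L, 4L, byrow = TRUE,
         dimnames = list(c("sW", "vW", "hW", "dW"),
                         c("all", "side", "task", "diag")))
}

#' Unit parameter-space direction that perturbs one connectivity eigenvalue
#'
#' The normalized column of A for the chosen eigenmode; independent of z,
#' and mutually orthogonal across modes.
#'
#' @param mode one of "all", "side", "task", "diag"
#' @return unit 4-vector in (sW, vW, hW, dW) space
#' @export
scEigmodeVector <- function(mode = c("all", "side", "task", "diag")) {
  mode <- match.arg(mode)
  v <- scEigModeBasis()[, mode]
  v / sqrt(sum(v^2))
}

#' The rapid-task-switching emergent property
#'
#' Pro and Anti accuracies with means 0.75 and variances 0.075^2, averaged
#' over \code{innerTrials} trials per task per draw.
#' @param innerTrials trials per task per parameter draw
#' @return an \linkS4class{EmergentProperty}
#' @export
scTaskSwitchProperty <- function(innerTrials = 200L) {
  emergentProperty(c("pP", "pA"), mu = c(0.75, 0.75),
                   sigma2 = c(0.075^2, 0.075^2), innerTrials = innerTrials)
}

## initialization in the net-inhibitory regime where the bounded response
## stays mid-range (lambda_all ~ -4) and task competition is possible
setMethod("defaultInit", "SCNetwork", function(model)
  list(mu = c(0.5, -2.5, -1.5, -0.5), sd = rep(1, 4)))

setMethod("defaultHyperparams", "SCNetwork", function(model)
  alHyperparams(c0 = 1e2, beta = 2, imax = 2000L, kmax = 10L, batchN = 100L,
                Ntest = 25L, testReps = 200L))
setMethod("defaultArchitecture", "SCNetwork", function(model)
  flowArchitecture(nCouplingStages = 3L, conditionerDepth = 2L,
                   conditionerWidth = 50L, dim = 4L))
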