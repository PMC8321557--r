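## Rank-2 RNN connectivity model: W = U V' with U = [U1 U2] + g*chi_U and
## V = [V1 V2] + g*chi_V. The nonzero eigenvalues of W equal those of the
## rank-reduced 2x2 matrix Wr = V'U, so real(lambda1) has a quadratic-formula
## closed form; lambda1s is the top eigenvalue of the symmetrized W with the
## standard eigenvector-outer-product derivative.

#' @rdname circuitModel
#' @param N number of neurons
#' @param g random connectivity strength
#' @export
rank2RNNModel <- function(N = 2L, g = 0.01) {
  new("Rank2RNN", N = as.integer(N), g = g)
}

setMethod("paramDim", "Rank2RNN", function(model) 4L * model@N)
setMethod("paramNames", "Rank2RNN", function(model) {
  as.vector(vapply(c("U1", "U2", "V1", "V2"),
                   function(p) paste0(p, "_", seq_len(model@N)),
                   character(model@N)))
})
setMethod("supportBox", "Rank2RNN", function(model)
  boxSupport(rep(-1, 4L * model@N), rep(1, 4L * model@N)))

#' Materialize rank-2 RNN connectivity from parameters
#'
#' Draws the Gaussian perturbations chi once (from \code{seed}) and returns
#' the factor matrices together with \code{W = U V'} and the rank-reduced
#' matrix \code{Wr = V' U}.
#'
#' @param z length-4N parameter vector (U1, U2, V1, V2)
#' @param g random strength
#' @param N number of neurons
#' @param seed integer seed for chi
#' @return list with U, V, W, Wr
#' @export
rnnBuild <- function(z, g, N, seed = 1L) {
  stopifnot(length(z) == 4L * N)
  chi <- seededNormals(2L * N, 2L, seed)
  U <- cbind(z[1:N], z[(N + 1):(2 * N)]) + g * chi[1:N, , drop = FALSE]
  V <- cbind(z[(2 * N + 1):(3 * N)], z[(3 * N + 1):(4 * N)]) +
    g * chi[(N + 1):(2 * N), , drop = FALSE]
  list(U = U, V = V, W = U %*% t(V), Wr = t(V) %*% U)
}

#' Eigenvalue statistics of the rank-2 RNN
#'
#' \code{real(lambda1)} from the trace/determinant formula on \code{Wr} and
#' \code{lambda1s}, the maximum eigenvalue of \code{(W + W')/2}.
#'
#' @inheritParams rnnBuild
#' @param withGrad also return the analytic gradient w.r.t. z?
#' @return list with \code{f = c(realLambda1, lambda1s)} and optionally
#'   \code{grad} (2 x 4N matrix)
#' @export
rnnStatistics <- function(z, g, N, seed = 1L, withGrad = FALSE) {
  b <- rnnBuild(z, g, N, seed)
  Wr <- b$Wr
  tr <- Wr[1, 1] + Wr[2, 2]
  dt <- Wr[1, 1] * Wr[2, 2] - Wr[1, 2] * Wr[2, 1]
  disc <- tr^2 - 4 * dt
  re1 <- if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
  Ws <- (b$W + t(b$W)) / 2
  es <- eigen(Ws, symmetric = TRUE)
  l1s <- es$values[1]
  out <- list(f = c(realLambda1 = re1, lambda1s = unname(l1s)))
  if (withGrad) {
    ## real(lambda1): chain through Wr = V'U
    dDetdWr <- matrix(c(Wr[2, 2], -Wr[1, 2], -Wr[2, 1], Wr[1, 1]), 2, 2)
    dTrdWr <- diag(2)
    M <- if (disc >= 0) {
      sq <- max(sqrt(disc), 1e-12)
      (dTrdWr + (2 * tr * dTrdWr - 4 * dDetdWr) / (2 * sq)) / 2
    } else dTrdWr / 2
    dRe_dU <- b$V %*% M          # dE/dU_{ib} = sum_a V_{ia} M_{ab}
    dRe_dV <- b$U %*% t(M)
    ## lambda1s: dE/dW = v1 v1', then W = U V'
    v1 <- es$vectors[, 1]
    P <- tcrossprod(v1)
    dLs_dU <- P %*% b$V
    dLs_dV <- t(P) %*% b$U
    out$grad <- rbind(c(dRe_dU[, 1], dRe_dU[, 2], dRe_dV[, 1], dRe_dV[, 2]),
                      c(dLs_dU[, 1], dLs_dU[, 2], dLs_dV[, 1], dLs_dV[, 2]))
  }
  out
}

## Fully vectorized batch statistics for N = 2, where both eigenvalue
## formulas and their gradients are closed-form in the 2x2 entries.
rnnStatisticsBatch2 <- function(z, g, seed, withGrad = FALSE) {
  n <- nrow(z)
  chi <- seededNormals(n, 8L, seed)   # per-row chi_U (4), chi_V (4)
  U11 <- z[, 1] + g * chi[, 1]; U21 <- z[, 2] + g * chi[, 2]
  U12 <- z[, 3] + g * chi[, 3]; U22 <- z[, 4] + g * chi[, 4]
  V11 <- z[, 5] + g * chi[, 5]; V21 <- z[, 6] + g * chi[, 6]
  V12 <- z[, 7] + g * chi[, 7]; V22 <- z[, 8] + g * chi[, 8]
  ## Wr = V'U (2x2): Wr_ab = sum_i V_ia U_ib
  Wr11 <- V11 * U11 + V21 * U21; Wr12 <- V11 * U12 + V21 * U22
  Wr21 <- V12 * U11 + V22 * U21; Wr22 <- V12 * U12 + V22 * U22
  tr <- Wr11 + Wr22; dt <- Wr11 * Wr22 - Wr12 * Wr21
  disc <- tr^2 - 4 * dt
  realCase <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  re1 <- ifelse(realCase, (tr + sq) / 2, tr / 2)
  ## W = U V' (2x2), symmetrized
  W11 <- U11 * V11 + U12 * V12; W12 <- U11 * V21 + U12 * V22
  W21 <- U21 * V11 + U22 * V12; W22 <- U21 * V21 + U22 * V22
  b <- (W12 + W21) / 2
  mid <- (W11 + W22) / 2; rad <- sqrt(((W11 - W22) / 2)^2 + b^2)
  l1s <- mid + rad
  f <- cbind(realLambda1 = re1, lambda1s = l1s)
  if (!withGrad) return(list(f = f, grad = NULL))
  ## d re1 / d Wr entries
  sqs <- pmax(sq, 1e-12)
  dTr <- ifelse(realCase, (1 + tr / sqs) / 2, 0.5)   # coefficient on dtr
  dDt <- ifelse(realCase, -1 / sqs, 0)               # coefficient on ddet
  M11 <- dTr + dDt * Wr22; M22 <- dTr + dDt * Wr11
  M12 <- -dDt * Wr21; M21 <- -dDt * Wr12
  ## careful: d det = Wr22 dWr11 - Wr21 dWr12 - Wr12 dWr21 + Wr11 dWr22
  ## dE/dU_ib = sum_a V_ia M_ab ; dE/dV_ia = sum_b M_ab U_ib
  G <- array(0, dim = c(n, 2L, 8L))
  G[, 1, 1] <- V11 * M11 + V12 * M21   # dU11 (z1)
  G[, 1, 2] <- V21 * M11 + V22 * M21   # dU21 (z2)
  G[, 1, 3] <- V11 * M12 + V12 * M22   # dU12 (z3)
  G[, 1, 4] <- V21 * M12 + V22 * M22   # dU22 (z4)
  G[, 1, 5] <- M11 * U11 + M12 * U12   # dV11 (z5)
  G[, 1, 6] <- M11 * U21 + M12 * U22   # dV21 (z6)
  G[, 1, 7] <- M21 * U11 + M22 * U12   # dV12 (z7)
  G[, 1, 8] <- M21 * U21 + M22 * U22   # dV22 (z8)
  ## eigvec of Ws for l1s: (b, l1s - W11) unless b ~ 0
  e1 <- ifelse(abs(b) > 1e-12, b, ifelse(W11 >= W22, 1, 0))
  e2 <- ifelse(abs(b) > 1e-12, l1s - W11, ifelse(W11 >= W22, 0, 1))
  nrm <- sqrt(e1^2 + e2^2); e1 <- e1 / nrm; e2 <- e2 / nrm
  P11 <- e1 * e1; P12 <- e1 * e2; P22 <- e2 * e2
  ## dE/dW = v1 v1'; dE/dU = (v1v1')V ; dE/dV = (v1v1')'U
  G[, 2, 1] <- P11 * V11 + P12 * V21
  G[, 2, 2] <- P12 * V11 + P22 * V21
  G[, 2, 3] <- P11 * V12 + P12 * V22
  G[, 2, 4] <- P12 * V12 + P22 * V22
  G[, 2, 5] <- P11 * U11 + P12 * U21
  G[, 2, 6] <- P12 * U11 + P22 * U21
  G[, 2, 7] <- P11 * U12 + P12 * U22
  G[, 2, 8] <- P12 * U12 + P22 * U22
  list(f = f, grad = G)
}

setMethod("circuitStatistics", "Rank2RNN",
  function(model, z, nTrials = 1L, seed = 1L, withGrad = FALSE) {
    z <- asPointMatrix(z, 4L * model@N)
    n <- nrow(z); D <- ncol(z)
    if (model@N == 2L && nTrials == 1L) {
      ## one chi draw per z, matching the per-row seed of the generic path
      return(rnnStatisticsBatch2(z, model@g, seed = childSeed(seed, 0L),
                                 withGrad = withGrad))
    }
    f <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("realLambda1", "lambda1s")))
    G <- if (withGrad) array(NA_real_, dim = c(n, 2L, D)) else NULL
    for (i in seq_len(n)) {
      acc <- matrix(0, nTrials, 2L)
      gacc <- if (withGrad) array(0, dim = c(nTrials, 2L, D)) else NULL
      for (tr in seq_len(nTrials)) {
        st <- rnnStatistics(z[i, ], model@g, model@N,
                            seed = childSeed(seed, (i - 1L) * nTrials + tr),
                            withGrad = withGrad)
        acc[tr, ] <- st$f
        if (withGrad) gacc[tr, , ] <- st$grad
      }
      f[i, ] <- colMeans(acc)
      if (withGrad) G[i, , ] <- apply(gacc, c(2, 3), mean)
    }
    list(f = f, grad = G)
  })

setMethod("simulateCircuit", "Rank2RNN",
  function(model, z, seed, x0 = NULL, tMax = 100, dt = 1, tau = 100, ...) {
    b <- rnnBuild(z, model@g, model@N, seed)
    if (is.null(x0)) x0 <- withSeed(childSeed(seed, 2L), rnorm(model@N))
    nT <- ceiling(tMax / dt)
    X <- matrix(NA_real_, model@N, nT)
    x <- x0
    for (t in seq_len(nT)) {
      x <- x + dt / tau * (-x + as.numeric(b$W %*% x))
      X[, t] <- x
    }
    X
  })

#' Classify a connectivity matrix by the stable-amplification conditions
#'
#' Stable amplification requires \code{real(lambda1) < 1} (stability) and
#' \code{lambda1s > 1} (transient growth of some input), with lambda1 the
#' eigenvalue of W of greatest real part and lambda1s the top eigenvalue of
#' the symmetrized connectivity.
#'
#' @param W a square connectivity matrix
#' @return one of \code{"stable amplified"}, \code{"stable monotonic decay"},
#'   \code{"unstable"}
#' @export
stableAmplificationCheck <- function(W) {
  re1 <- max(Re(eigen(W, only.values = TRUE)$values))
  l1s <- max(eigen((W + t(W)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  if (re1 >= 1) "unstable"
  else if (l1s > 1) "stable amplified"
  else "stable monotonic decay"
}

#' The stable-amplification emergent property
#'
#' Means (0.5, 1.5) and variances (0.25^2, 0.25^2) for
#' (real(lambda1), lambda1s), placing most of the distribution inside the
#' stable-amplification regime.
#' @return an \linkS4class{EmergentProperty}
#' @export
rnnStableAmplificationProperty <- function() {
  emergentProperty(c("realLambda1", "lambda1s"), mu = c(0.5, 1.5),
                   sigma2 = c(0.25^2, 0.25^2), innerTrials = 1L)
}

setMethod("defaultHyperparams", "Rank2RNN", function(model)
  alHyperparams(c0 = 1e3, beta = 4, imax = 500L, kmax = 10L, batchN = 200L,
                Ntest = 200L, testReps = 200L))
setMethod("defaultArchitecture", "Rank2RNN", function(model)
  flowArchitecture(nCouplingStages = 3L, conditionerDepth = 2L,
                   conditionerWidth = 100L, dim = 4L * model@N))
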