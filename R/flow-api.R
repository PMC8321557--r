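## User-facing flow operations built on the forward/inverse passes.

#' Draw samples from a flow distribution
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param n number of samples (n = 0 gives empty outputs)
#' @param seed integer seed
#' @return list with \code{z} (n x D matrix), \code{logDensity} (length n,
#'   equal to \code{logProb(flow, z)}), and \code{z0} (the base draws)
#' @export
sampleFlow <- function(flow, n, seed = 1L) {
  D <- flow@architecture@dim
  n <- as.integer(n)
  if (n == 0L) {
    return(list(z = matrix(numeric(0), 0L, D), logDensity = numeric(0),
                z0 = matrix(numeric(0), 0L, D)))
  }
  Z0 <- seededNormals(n, D, seed)
  fw <- flowForward(flow, Z0)
  list(z = fw$z, logDensity = fw$logq, z0 = Z0)
}

#' Exact log density of a flow at given points
#'
#' Change-of-variables density through the inverse coupling stack and the
#' support map. Points outside the open support box get \code{-Inf} (default)
#' or raise an error, per \code{outOfSupport}.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param z numeric vector (one point) or n x D matrix of points
#' @param outOfSupport \code{"neginf"} or \code{"error"}
#' @return numeric vector of log densities
#' @export
logProb <- function(flow, z, outOfSupport = c("neginf", "error")) {
  outOfSupport <- match.arg(outOfSupport)
  Z <- asPointMatrix(z, flow@architecture@dim)
  inv <- flowInverse(flow, Z)
  lq <- inv$logq
  bad <- !is.finite(rowSums(inv$z0))
  if (any(bad)) {
    if (outOfSupport == "error")
      stop("logProb: ", sum(bad), " point(s) outside the support box",
           call. = FALSE)
    lq[bad] <- -Inf
  }
  lq
}

#' Analytic gradient of the flow log density with respect to z
#'
#' Reverse-mode differentiation through the inverse pass (inverse couplings,
#' conditioner networks and support map), yielding the exact gradient of
#' \code{logProb} at interior points.
#'
#' @inheritParams logProb
#' @return n x D matrix of gradients
#' @export
logProbGrad <- function(flow, z) {
  lay <- flow@layout; theta <- flow@weights
  Z <- asPointMatrix(z, lay$D)
  inv <- flowInverse(flow, Z, keepCache = TRUE)
  if (any(!is.finite(rowSums(inv$z0))))
    stop("logProbGrad: point(s) outside the open support box", call. = FALSE)
  n <- nrow(Z)
  dY <- -inv$z0                       # d logp0 / d z0
  if (!isTRUE(lay$affineOnly)) {
    for (s in seq_len(lay$L)) {
      dY <- dY[, lay$perms[[s]], drop = FALSE]   # undo trailing inverse perm
      sc <- inv$cache$stages[[s]]
      idA <- lay$idA[[s]]; idB <- lay$idB[[s]]
      dBc <- dY[, idB, drop = FALSE]
      dAc <- dY[, idA, drop = FALSE]
      eNeg <- exp(-sc$scl)
      dBp <- dBc * eNeg
      dt <- -dBp
      dscl <- -dBc * sc$B - 1         # -1: logq subtracts rowSums(scl)
      dsraw <- dscl * clampScaleDeriv(sc$scl)
      dAc <- dAc + mlpBackward(theta, lay$mlps[[s]], sc$mlp,
                               cbind(dt, dsraw), gradEnv = NULL)
      dY[, idA] <- dAc
      dY[, idB] <- dBp
    }
  } else {
    dY <- dY * exp(-clampScale(theta[2L]))
  }
  ## support map: gradient of -logdet_sup(y) plus chain rule dy/dz
  cs <- inv$cache$cs
  dY <- dY + supportBackward(cs, flow@support,
                             matrix(0, n, lay$D), rep(-1, n))
  lo <- flow@support@lower; up <- flow@support@upper
  kind <- cs$kind
  for (j in seq_len(lay$D)) {
    s <- cs$sig[, j]
    if (kind[j] == 1L) {
      dY[, j] <- dY[, j] / ((up[j] - lo[j]) * s * (1 - s))
    } else if (kind[j] == 2L || kind[j] == 3L) {
      dY[, j] <- dY[, j] / s
    }
  }
  dY
}

#' Monte-Carlo entropy estimate of a flow
#'
#' Mean of \code{-log q} over n fresh samples (reparameterized), with its
#' standard error.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param n number of samples (>= 2)
#' @param seed integer seed
#' @return list with \code{entropy} (nats) and \code{se}
#' @export
entropyEstimate <- function(flow, n, seed = 1L) {
  stopifnot(n >= 2L)
  s <- sampleFlow(flow, n, seed)
  h <- -s$logDensity
  list(entropy = mean(h), se = sd(h) / sqrt(n))
}

asPointMatrix <- function(z, D) {
  if (is.null(dim(z))) {
    if (length(z) != D) stop("point has wrong dimension", call. = FALSE)
    matrix(z, 1L, D)
  } else {
    if (ncol(z) != D) stop("points have wrong dimension", call. = FALSE)
    as.matrix(z)
  }
}

## ---------------------------------------------------------------- Adam

adamInit <- function(nPar) {
  list(m = numeric(nPar), v = numeric(nPar), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamStep <- function(state, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + state$eps)
  state
}

## -------------------------------------------------- Gaussian initialization

#' Fit a flow to an isotropic (or diagonal) Gaussian
#'
#' Stochastic gradient descent on the reverse KL divergence between the flow
#' and a diagonal Gaussian target, using the reparameterization trick. Used to
#' initialize EPI optimization at a chosen mean and variance inside the
#' support.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param muInit target mean (must lie inside the support box)
#' @param varInit target variance (scalar or per-dimension)
#' @param iters SGD iterations
#' @param lr Adam learning rate
#' @param seed integer seed
#' @param batchN samples per iteration
#' @return the fitted \linkS4class{FlowDistribution}
#' @export
fitToGaussian <- function(flow, muInit, varInit, iters = 10000L, lr = 1e-3,
                          seed = 1L, batchN = 200L) {
  D <- flow@architecture@dim
  muInit <- rep_len(as.numeric(muInit), D)
  varInit <- rep_len(as.numeric(varInit), D)
  lo <- flow@support@lower; up <- flow@support@upper
  if (any(muInit <= lo | muInit >= up))
    stop("fitToGaussian: muInit must lie strictly inside the support",
         call. = FALSE)
  theta <- flow@weights
  ad <- adamInit(length(theta))
  for (it in seq_len(iters)) {
    Z0 <- seededNormals(batchN, D, childSeed(seed, it))
    fl <- flow; fl@weights <- theta
    fw <- flowForward(fl, Z0, keepCache = TRUE)
    ## loss = mean(log q(z) - log N(z; mu, var))
    dZ <- sweep(sweep(fw$z, 2L, muInit, "-"), 2L, varInit, "/") / batchN
    dLogdet <- rep(-1 / batchN, batchN)
    g <- flowBackward(fl, fw$cache, dZ, dLogdet)
    if (!all(is.finite(g)))
      stop("fitToGaussian: non-finite gradient at iteration ", it,
           call. = FALSE)
    ad <- adamStep(ad, g, lr)
    theta <- theta - ad$step
  }
  flow@weights <- theta
  flow
}

## ---------------------------------------------------------- serialization

#' Serialize a flow to JSON
#'
#' Writes weights, architecture and support so the flow reloads exactly.
#' @param flow a \linkS4class{FlowDistribution}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
saveFlow <- function(flow, path) {
  arch <- flow@architecture
  obj <- list(
    architecture = list(nCouplingStages = arch@nCouplingStages,
                        conditionerDepth = arch@conditionerDepth,
                        conditionerWidth = arch@conditionerWidth,
                        permutation = arch@permutation, dim = arch@dim),
    support = list(lower = flow@support@lower, upper = flow@support@upper),
    permutations = if (isTRUE(flow@layout$affineOnly)) list()
                   else flow@layout$perms,
    weights = flow@weights)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveFlow
#' @param path JSON file written by \code{saveFlow}
#' @export
loadFlow <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- obj$architecture
  arch <- flowArchitecture(a$nCouplingStages, a$conditionerDepth,
                           a$conditionerWidth, a$permutation, a$dim)
  sup <- boxSupport(obj$support$lower, obj$support$upper)
  fl <- buildFlow(arch, sup, seed = 1L)
  if (!isTRUE(fl@layout$affineOnly)) {
    perms <- if (is.matrix(obj$permutations))
      lapply(seq_len(nrow(obj$permutations)),
             function(i) as.integer(obj$permutations[i, ]))
    else lapply(obj$permutations, as.integer)
    fl@layout$perms <- perms
    fl@layout$invPerms <- lapply(perms, order)
  }
  fl@weights <- as.numeric(obj$weights)
  validObject(fl)
  fl
}
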