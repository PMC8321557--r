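## Real NVP coupling stack with exact inverse and hand-written reverse-mode
## gradients. Everything is batched: points are rows of n x D matrices.
##
## Forward direction (sampling): z0 ~ N(0, I) -> [perm, affine coupling] x L
## -> support map -> z. Each coupling transforms one half of the coordinates
## with a shift and a (smoothly clamped) log-scale produced by a tanh MLP
## conditioned on the other half; halves alternate between stages. The
## Jacobian is triangular, so log|det| is the row sum of the log-scales plus
## the elementwise support-map term.

SCLAMP <- 5  # log-scale saturation: s = SCLAMP * tanh(s_raw / SCLAMP)

clampScale <- function(sraw) SCLAMP * tanh(sraw / SCLAMP)
clampScaleDeriv <- function(scl) 1 - (scl / SCLAMP)^2

## ------------------------------------------------------------------ build

#' Construct and initialize a flow distribution
#'
#' Conditioner hidden weights are Gaussian with standard deviation
#' 1/sqrt(fan-in); the output layer is zero-initialized so a freshly built
#' flow is the identity transform of its base variable (composed with the
#' support map), i.e. the base Gaussian pushed into the support box.
#'
#' @param arch a \linkS4class{FlowArchitecture}
#' @param support a \linkS4class{BoxSupport} of matching dimension
#' @param seed integer seed for weight initialization and permutations
#' @return a \linkS4class{FlowDistribution}
#' @examples
#' fl <- buildFlow(flowArchitecture(dim = 2L),
#'                 boxSupport(c(0, 0), c(1, 1)), seed = 1L)
#' s <- sampleFlow(fl, 100L, seed = 2L)
#' stopifnot(all(s$z > 0 & s$z < 1))
#' @export
buildFlow <- function(arch, support, seed = 1L) {
  validObject(arch); validObject(support)
  D <- arch@dim
  if (length(support@lower) != D)
    stop("flow configuration error: support dimension (", length(support@lower),
         ") does not match architecture dim (", D, ")", call. = FALSE)
  layout <- flowLayout(arch, seed)
  weights <- withSeed(childSeed(seed, 1L), initWeights(layout))
  new("FlowDistribution", architecture = arch, support = support,
      weights = weights, layout = layout)
}

#' @rdname buildFlow
#' @param nCouplingStages,conditionerDepth,conditionerWidth,permutation,dim
#'   see \linkS4class{FlowArchitecture}
#' @export
flowArchitecture <- function(nCouplingStages = 3L, conditionerDepth = 2L,
                             conditionerWidth = 50L, permutation = "glow",
                             dim = 2L) {
  new("FlowArchitecture", nCouplingStages = as.integer(nCouplingStages),
      conditionerDepth = as.integer(conditionerDepth),
      conditionerWidth = as.integer(conditionerWidth),
      permutation = permutation, dim = as.integer(dim))
}

#' @rdname buildFlow
#' @param lower,upper per-dimension bounds; use -Inf/Inf for open ends
#' @export
boxSupport <- function(lower, upper) {
  new("BoxSupport", lower = as.numeric(lower), upper = as.numeric(upper))
}

## Weight/mask layout. For D = 1 couplings are impossible; a single global
## affine stage (shift, log-scale) is used instead.
flowLayout <- function(arch, seed) {
  D <- arch@dim; L <- arch@nCouplingStages
  if (D == 1L) {
    return(list(D = 1L, L = 0L, affineOnly = TRUE, nParams = 2L))
  }
  d1 <- ceiling(D / 2)  # odd D: extra coordinate in the first half
  idA <- vector("list", L); idB <- vector("list", L)
  for (s in seq_len(L)) {
    if (arch@permutation != "glow" || s %% 2L == 1L) {
      ## fixed-swap alternates via the swap itself; glow alternates masks
      idA[[s]] <- seq_len(d1); idB[[s]] <- (d1 + 1L):D
    } else {
      idA[[s]] <- (D - d1 + 1L):D; idB[[s]] <- seq_len(D - d1)
    }
  }
  permSeed <- childSeed(seed, 2L)
  ## every coordinate must fall in some stage's transformed half, or it
  ## would pass through the whole stack untrained; redraw (deterministically)
  ## until the permutations cover all coordinates
  for (attempt in 0:100) {
    perms <- vector("list", L)
    for (s in seq_len(L)) {
      perms[[s]] <- if (s == 1L) {
        seq_len(D)
      } else if (arch@permutation == "glow") {
        withSeed(childSeed(permSeed, s + 1000L * attempt), sample.int(D))
      } else {
        c((d1 + 1L):D, 1L:d1)  # fixed-swap
      }
    }
    slotAt <- seq_len(D)        # output slot held at each position
    transformed <- rep(FALSE, D)
    for (s in seq_len(L)) {
      slotAt <- slotAt[perms[[s]]]
      transformed[slotAt[idB[[s]]]] <- TRUE
    }
    ## a single coupling stage inherently leaves one half untransformed;
    ## coverage is only enforceable (and guaranteed findable) for L >= 2
    if (all(transformed) || arch@permutation != "glow" || L == 1L) break
  }
  if (L >= 2L && !all(transformed))
    stop("buildFlow: could not find covering permutations", call. = FALSE)
  mlps <- vector("list", L); off <- 0L
  for (s in seq_len(L)) {
    sizes <- c(length(idA[[s]]),
               rep(arch@conditionerWidth, arch@conditionerDepth),
               2L * length(idB[[s]]))
    layers <- vector("list", length(sizes) - 1L)
    for (l in seq_along(layers)) {
      nin <- sizes[l]; nout <- sizes[l + 1L]
      layers[[l]] <- list(nin = nin, nout = nout,
                          wIdx = off + seq_len(nin * nout),
                          bIdx = off + nin * nout + seq_len(nout))
      off <- off + nin * nout + nout
    }
    mlps[[s]] <- list(sizes = sizes, layers = layers)
  }
  list(D = D, L = L, affineOnly = FALSE, d1 = d1, perms = perms,
       invPerms = lapply(perms, order), idA = idA, idB = idB,
       mlps = mlps, nParams = off)
}

initWeights <- function(layout) {
  if (isTRUE(layout$affineOnly)) return(c(0, 0))
  w <- numeric(layout$nParams)
  for (s in seq_len(layout$L)) {
    layers <- layout$mlps[[s]]$layers
    nl <- length(layers)
    for (l in seq_len(nl - 1L)) {  # final layer stays zero -> identity flow
      lay <- layers[[l]]
      w[lay$wIdx] <- rnorm(length(lay$wIdx), sd = 1 / sqrt(lay$nin))
    }
  }
  w
}

#' Number of weights of a flow architecture
#' @param arch a \linkS4class{FlowArchitecture}
#' @return integer parameter count (deterministic in the architecture)
#' @export
nFlowParams <- function(arch) flowLayout(arch, seed = 1L)$nParams

## ------------------------------------------------------------ MLP pieces

mlpForward <- function(theta, mlp, A) {
  layers <- mlp$layers; nl <- length(layers)
  acts <- vector("list", nl)  # post-activation of hidden layers; input is A
  H <- A
  for (l in seq_len(nl)) {
    lay <- layers[[l]]
    W <- matrix(theta[lay$wIdx], lay$nin, lay$nout)
    Z <- H %*% W + rep(theta[lay$bIdx], each = nrow(H))
    H <- if (l < nl) tanh(Z) else Z
    acts[[l]] <- H
  }
  list(out = H, acts = acts, input = A)
}

## dOut: cotangent of the MLP output. Returns input cotangent and adds the
## weight gradient into `gradEnv$g` (a preallocated numeric vector).
mlpBackward <- function(theta, mlp, cache, dOut, gradEnv = NULL) {
  layers <- mlp$layers; nl <- length(layers)
  dH <- dOut
  for (l in rev(seq_len(nl))) {
    lay <- layers[[l]]
    inp <- if (l == 1L) cache$input else cache$acts[[l - 1L]]
    if (l < nl) dH <- dH * (1 - cache$acts[[l]]^2)  # tanh'
    if (!is.null(gradEnv)) {
      gradEnv$g[lay$wIdx] <- gradEnv$g[lay$wIdx] + as.numeric(crossprod(inp, dH))
      gradEnv$g[lay$bIdx] <- gradEnv$g[lay$bIdx] + colSums(dH)
    }
    W <- matrix(theta[lay$wIdx], lay$nin, lay$nout)
    dH <- dH %*% t(W)
  }
  dH  # cotangent of the input A
}

## ------------------------------------------------------- support mapping

supportKind <- function(support) {
  lo <- support@lower; up <- support@upper
  ifelse(is.finite(lo) & is.finite(up), 1L,
         ifelse(is.finite(lo), 2L, ifelse(is.finite(up), 3L, 0L)))
}

## y (n x D) -> z in the box; also per-row logdet and caches for backward
supportForward <- function(Y, support) {
  lo <- support@lower; up <- support@upper
  kind <- supportKind(support); n <- nrow(Y)
  Z <- Y; LD <- matrix(0, n, ncol(Y)); SIG <- matrix(NA_real_, n, ncol(Y))
  for (j in seq_along(kind)) {
    yj <- Y[, j]
    if (kind[j] == 1L) {
      s <- sigmoid(yj); SIG[, j] <- s
      Z[, j] <- lo[j] + (up[j] - lo[j]) * s
      LD[, j] <- log(up[j] - lo[j]) + logSigmoid(yj) + logSigmoid(-yj)
    } else if (kind[j] == 2L) {
      Z[, j] <- lo[j] + softplus(yj)
      LD[, j] <- logSigmoid(yj); SIG[, j] <- sigmoid(yj)
    } else if (kind[j] == 3L) {
      Z[, j] <- up[j] - softplus(-yj)
      LD[, j] <- logSigmoid(-yj); SIG[, j] <- sigmoid(-yj)
    }
  }
  list(Z = Z, logdet = rowSums(LD), sig = SIG, kind = kind)
}

## cotangent through the support map: given dZ and per-row dLogdet weight
supportBackward <- function(cacheS, support, dZ, dLogdet) {
  lo <- support@lower; up <- support@upper
  kind <- cacheS$kind; SIG <- cacheS$sig
  dY <- dZ
  for (j in seq_along(kind)) {
    s <- SIG[, j]
    if (kind[j] == 1L) {
      dY[, j] <- dZ[, j] * (up[j] - lo[j]) * s * (1 - s) + dLogdet * (1 - 2 * s)
    } else if (kind[j] == 2L) {
      dY[, j] <- dZ[, j] * s + dLogdet * (1 - s)
    } else if (kind[j] == 3L) {
      dY[, j] <- dZ[, j] * s - dLogdet * (1 - s)
    }
    ## unbounded: identity, zero logdet
  }
  dY
}

## z -> y (inverse support map); NA where z is outside the open box
supportInverse <- function(Z, support) {
  lo <- support@lower; up <- support@upper
  kind <- supportKind(support)
  Y <- Z
  for (j in seq_along(kind)) {
    zj <- Z[, j]
    if (kind[j] == 1L) {
      u <- (zj - lo[j]) / (up[j] - lo[j])
      bad <- u <= 0 | u >= 1
      u[bad] <- NA_real_
      Y[, j] <- logit(u)
    } else if (kind[j] == 2L) {
      d <- zj - lo[j]; d[d <= 0] <- NA_real_
      Y[, j] <- softplusInv(d)
    } else if (kind[j] == 3L) {
      d <- up[j] - zj; d[d <= 0] <- NA_real_
      Y[, j] <- -softplusInv(d)
    }
  }
  Y
}

## ------------------------------------------------------------ forward pass

## Z0: n x D base draws. Returns z, logdet, logq and (optionally) caches.
flowForward <- function(flow, Z0, keepCache = FALSE) {
  lay <- flow@layout; theta <- flow@weights
  n <- nrow(Z0)
  logdet <- numeric(n)
  if (isTRUE(lay$affineOnly)) {
    scl <- clampScale(theta[2L])
    Y <- theta[1L] + exp(scl) * Z0
    logdet <- logdet + scl
    cs <- supportForward(Y, flow@support)
    logq <- rowLogDnorm(Z0) - (logdet + cs$logdet)
    return(list(z = cs$Z, logdet = logdet + cs$logdet, logq = logq,
                cache = if (keepCache) list(Z0 = Z0, Y = Y, cs = cs) else NULL))
  }
  Y <- Z0
  stageCaches <- if (keepCache) vector("list", lay$L) else NULL
  for (s in seq_len(lay$L)) {
    Y <- Y[, lay$perms[[s]], drop = FALSE]
    A <- Y[, lay$idA[[s]], drop = FALSE]
    B <- Y[, lay$idB[[s]], drop = FALSE]
    mf <- mlpForward(theta, lay$mlps[[s]], A)
    dB <- length(lay$idB[[s]])
    tt <- mf$out[, seq_len(dB), drop = FALSE]
    scl <- clampScale(mf$out[, dB + seq_len(dB), drop = FALSE])
    eS <- exp(scl)
    Y[, lay$idB[[s]]] <- B * eS + tt
    logdet <- logdet + rowSums(scl)
    if (keepCache)
      stageCaches[[s]] <- list(mlp = mf, B = B, scl = scl, eS = eS)
  }
  cs <- supportForward(Y, flow@support)
  logq <- rowLogDnorm(Z0) - (logdet + cs$logdet)
  list(z = cs$Z, logdet = logdet + cs$logdet, logq = logq,
       cache = if (keepCache) list(Z0 = Z0, stages = stageCaches, cs = cs)
               else NULL)
}

## Reverse-mode through the forward pass: given per-sample cotangents of the
## output z (dZ, n x D; may be NULL) and of the total logdet (dLogdet, n),
## return the gradient with respect to the flat weights.
flowBackward <- function(flow, cache, dZ = NULL, dLogdet = NULL) {
  lay <- flow@layout; theta <- flow@weights
  n <- nrow(cache$Z0)
  if (is.null(dZ)) dZ <- matrix(0, n, lay$D)
  if (is.null(dLogdet)) dLogdet <- numeric(n)
  if (isTRUE(lay$affineOnly)) {
    dY <- supportBackward(cache$cs, flow@support, dZ, dLogdet)
    scl <- clampScale(theta[2L])
    g1 <- sum(dY)
    dscl <- sum(dY * cache$Z0 * exp(scl)) + sum(dLogdet)
    g2 <- dscl * clampScaleDeriv(scl)
    return(c(g1, g2))
  }
  gradEnv <- new.env(); gradEnv$g <- numeric(lay$nParams)
  dY <- supportBackward(cache$cs, flow@support, dZ, dLogdet)
  for (s in rev(seq_len(lay$L))) {
    sc <- cache$stages[[s]]
    idA <- lay$idA[[s]]; idB <- lay$idB[[s]]
    dBp <- dY[, idB, drop = FALSE]
    dA <- dY[, idA, drop = FALSE]
    dB <- dBp * sc$eS
    dt <- dBp
    dscl <- dBp * sc$B * sc$eS + dLogdet          # logdet adds rowSums(scl)
    dsraw <- dscl * clampScaleDeriv(sc$scl)
    dA <- dA + mlpBackward(theta, lay$mlps[[s]], sc$mlp,
                           cbind(dt, dsraw), gradEnv)
    dY[, idA] <- dA
    dY[, idB] <- dB
    dY <- dY[, lay$invPerms[[s]], drop = FALSE]
  }
  gradEnv$g
}

## ------------------------------------------------------------ inverse pass

## Exact inverse z -> z0 with the same logdet bookkeeping; caches support
## the analytic input-gradient of log q.
flowInverse <- function(flow, Z, keepCache = FALSE) {
  lay <- flow@layout; theta <- flow@weights
  Y <- supportInverse(Z, flow@support)
  cs <- supportForward(Y, flow@support)   # logdet + sigmoid caches at y
  logdet <- cs$logdet
  if (isTRUE(lay$affineOnly)) {
    scl <- clampScale(theta[2L])
    Z0 <- (Y - theta[1L]) * exp(-scl)
    logdet <- logdet + scl
    return(list(z0 = Z0, logdet = logdet, logq = rowLogDnorm(Z0) - logdet,
                cache = if (keepCache) list(Y = Y, cs = cs) else NULL))
  }
  stageCaches <- if (keepCache) vector("list", lay$L) else NULL
  for (s in rev(seq_len(lay$L))) {
    A <- Y[, lay$idA[[s]], drop = FALSE]
    Bp <- Y[, lay$idB[[s]], drop = FALSE]
    mf <- mlpForward(theta, lay$mlps[[s]], A)
    dB <- length(lay$idB[[s]])
    tt <- mf$out[, seq_len(dB), drop = FALSE]
    scl <- clampScale(mf$out[, dB + seq_len(dB), drop = FALSE])
    B <- (Bp - tt) * exp(-scl)
    Y[, lay$idB[[s]]] <- B
    logdet <- logdet + rowSums(scl)
    if (keepCache) stageCaches[[s]] <- list(mlp = mf, B = B, scl = scl)
    Y <- Y[, lay$invPerms[[s]], drop = FALSE]
  }
  list(z0 = Y, logdet = logdet, logq = rowLogDnorm(Y) - logdet,
       cache = if (keepCache) list(stages = stageCaches, cs = cs) else NULL)
}
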