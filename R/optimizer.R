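## Augmented-Lagrangian maximum-entropy training of the flow (Algorithm:
## epochs of Adam iterations at fixed multipliers eta and penalty c, followed
## by eta/c updates, an Adam reset, and a convergence hypothesis test).

#' Construct augmented-Lagrangian hyperparameters
#'
#' @param c0 initial penalty coefficient
#' @param beta penalty growth factor (> 1)
#' @param gamma required reduction ratio of the constraint norm per epoch
#' @param imax Adam iterations per epoch
#' @param kmax maximum epochs
#' @param batchN samples per iteration (even)
#' @param lr Adam learning rate
#' @param Ntest convergence-test batch size
#' @param testReps convergence-test replicates
#' @return an \linkS4class{ALHyperparams}
#' @export
alHyperparams <- function(c0 = 10, beta = 2, gamma = 0.25, imax = 1000L,
                          kmax = 10L, batchN = 200L, lr = 1e-3, Ntest = 100L,
                          testReps = 200L) {
  new("ALHyperparams", c0 = c0, beta = beta, gamma = gamma,
      imax = as.integer(imax), kmax = as.integer(kmax),
      batchN = as.integer(batchN), lr = lr, Ntest = as.integer(Ntest),
      testReps = as.integer(testReps))
}

#' Stochastic augmented-Lagrangian objective and its weight gradient
#'
#' Loss \code{-H(q) + eta' R + (c/2) ||R||^2} estimated on one batch. The
#' entropy gradient uses the reparameterization trick (it reduces to the
#' gradient of the log-det-Jacobian). The quadratic penalty's gradient is the
#' product of constraint averages over two independent half-batches, an
#' unbiased estimate of the product-of-expectations structure of
#' \code{grad ||R||^2}.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param model a \linkS4class{CircuitModel}
#' @param suff a \linkS4class{SufficientStatistics}
#' @param eta Lagrange multipliers (length m)
#' @param cpen penalty coefficient
#' @param batchN batch size (even)
#' @param seed integer seed
#' @return list with \code{loss}, \code{grad} (w.r.t. flow weights),
#'   \code{Rhat} (full-batch constraint violation), \code{normR},
#'   \code{entropy}, \code{nBad}
#' @export
alObjective <- function(flow, model, suff, eta, cpen, batchN, seed = 1L) {
  if (batchN %% 2L != 0L)
    stop("alObjective: batchN must be even for the half-batch estimator",
         call. = FALSE)
  D <- flow@architecture@dim
  Z0 <- seededNormals(batchN, D, childSeed(seed, 1L))
  fw <- flowForward(flow, Z0, keepCache = TRUE)
  ss <- suffStatsBatch(model, suff, fw$z, seed = childSeed(seed, 2L),
                       withGrad = TRUE)
  Tm <- ss$T
  ok <- is.finite(rowSums(Tm)) &
    is.finite(rowSums(matrix(ss$grad, nrow = batchN)))
  if (mean(!ok) > 0.10)
    stop("alObjective: more than 10% of the batch produced non-finite ",
         "statistics (", sum(!ok), "/", batchN, ")", call. = FALSE)
  if (any(!ok)) { Tm[!ok, ] <- 0; ss$grad[!ok, , ] <- 0 }
  nOk <- sum(ok)
  half1 <- seq_len(batchN / 2L); half2 <- (batchN / 2L + 1L):batchN
  dev <- sweep(Tm, 2L, suff@muOpt, "-"); dev[!ok, ] <- 0
  Rhat <- colSums(dev) / nOk
  R2 <- colSums(dev[half2, , drop = FALSE]) / max(sum(ok[half2]), 1L)
  entropy <- mean(-fw$logq[ok])
  loss <- -entropy + sum(eta * Rhat) + cpen / 2 * sum(Rhat^2)
  ## per-sample cotangents of z: (dT/dz)' a_j
  m <- nConstraints(suff)
  aAll <- matrix(eta / nOk, batchN, m, byrow = TRUE)
  aAll[half1, ] <- aAll[half1, , drop = FALSE] +
    matrix(cpen * R2 / nOk, length(half1), m, byrow = TRUE)
  aAll[!ok, ] <- 0
  dZ <- matrix(0, batchN, D)
  for (k in seq_len(m)) dZ <- dZ + aAll[, k] * ss$grad[, k, ]
  dLogdet <- ifelse(ok, -1 / nOk, 0)   # gradient of -H
  g <- flowBackward(flow, fw$cache, dZ, dLogdet)
  if (!all(is.finite(g)))
    stop("alObjective: non-finite gradient", call. = FALSE)
  list(loss = loss, grad = g, Rhat = Rhat, normR = sqrt(sum(Rhat^2)),
       entropy = entropy, nBad = sum(!ok))
}

#' Lagrange-multiplier update
#'
#' \code{eta' = eta + c * Rhat}.
#' @param eta current multipliers
#' @param cpen penalty coefficient
#' @param Rhat batch-mean constraint violation
#' @export
updateEta <- function(eta, cpen, Rhat) {
  stopifnot(length(eta) == length(Rhat))
  eta + cpen * Rhat
}

#' Stochastic penalty-coefficient update
#'
#' One-sided Welch comparison of the current epoch's constraint-norm samples
#' against \code{gamma} times the previous epoch's:
#' p approximates P(E[||R_k+1||] > gamma * E[||R_k||]), and the penalty grows
#' to \code{beta * c} with probability 1 - p.
#'
#' @param cpen current penalty coefficient
#' @param normsPrev,normsCurr per-batch ||R|| samples from consecutive epochs
#' @param gamma,beta reduction ratio and growth factor
#' @param seed integer seed for the Bernoulli draw
#' @return list with \code{c}, \code{p}, \code{updated}
#' @export
updateC <- function(cpen, normsPrev, normsCurr, gamma = 0.25, beta = 2,
                    seed = 1L) {
  stopifnot(length(normsPrev) >= 1L, length(normsCurr) >= 1L)
  m1 <- mean(normsCurr); m0 <- gamma * mean(normsPrev)
  v1 <- var(normsCurr) / length(normsCurr)
  v0 <- gamma^2 * var(normsPrev) / length(normsPrev)
  v1 <- if (is.finite(v1)) v1 else 0
  v0 <- if (is.finite(v0)) v0 else 0
  sediff <- sqrt(v1 + v0)
  if (sediff == 0) {
    p <- as.numeric(m1 >= m0)
  } else {
    tstat <- (m1 - m0) / sediff
    df <- max(1, (v1 + v0)^2 /
                (v1^2 / max(length(normsCurr) - 1, 1) +
                 v0^2 / max(length(normsPrev) - 1, 1) + 1e-300))
    p <- pt(tstat, df)
  }
  upd <- withSeed(seed, runif(1)) < (1 - p)
  list(c = if (upd) beta * cpen else cpen, p = p, updated = upd)
}

#' Run emergent property inference (augmented-Lagrangian maximum entropy)
#'
#' Initializes the flow at a Gaussian inside the support (unless
#' \code{gaussInitIters = 0}), then alternates epochs of Adam iterations on
#' the augmented-Lagrangian objective with multiplier/penalty updates, an
#' Adam-state reset, and the convergence hypothesis test. Among converged
#' epochs the one of greatest entropy is returned.
#'
#' @param model a \linkS4class{CircuitModel}
#' @param ep an \linkS4class{EmergentProperty}
#' @param flow optional pre-built flow (default: the model's default
#'   architecture on its support box)
#' @param hyper optional \linkS4class{ALHyperparams} (default:
#'   \code{defaultHyperparams(model)})
#' @param seed integer seed governing all randomness of the run
#' @param muInit,sdInit Gaussian initialization; defaults to
#'   \code{defaultInit(model)} (box center and 1/8 width for most models)
#' @param gaussInitIters SGD iterations of the Gaussian initialization
#' @param alpha significance level of the convergence test
#' @param entropyN samples for the per-epoch entropy estimate
#' @param logFile optional JSON-lines metrics file (appended every
#'   \code{logEvery} iterations)
#' @param logEvery iteration logging cadence
#' @param verbose print per-epoch summaries?
#' @return an \linkS4class{EPIResult}
#' @export
epiFit <- function(model, ep, flow = NULL, hyper = NULL, seed = 1L,
                   muInit = NULL, sdInit = NULL, gaussInitIters = 1000L,
                   alpha = 0.05, entropyN = 1000L, logFile = NULL,
                   logEvery = 100L, verbose = FALSE) {
  if (is.null(hyper)) hyper <- defaultHyperparams(model)
  validObject(hyper)
  suff <- makeConstraints(ep)
  m <- nConstraints(suff)
  sup <- supportBox(model)
  if (is.null(flow)) flow <- buildFlow(defaultArchitecture(model), sup,
                                       seed = childSeed(seed, 101L))
  if (gaussInitIters > 0L) {
    init <- defaultInit(model)
    if (is.null(muInit)) muInit <- init$mu
    if (is.null(sdInit)) sdInit <- init$sd
    flow <- fitToGaussian(flow, muInit, sdInit^2, iters = gaussInitIters,
                          lr = 1e-3, seed = childSeed(seed, 102L),
                          batchN = max(hyper@batchN, 100L))
  }
  eta <- numeric(m); cpen <- hyper@c0
  theta <- flow@weights
  hist <- list()
  snapshots <- list()
  normsPrev <- NULL
  bestEpoch <- NA_integer_
  logCon <- if (!is.null(logFile)) file(logFile, open = "a") else NULL
  on.exit(if (!is.null(logCon)) close(logCon), add = TRUE)
  lastEntropy <- NA_real_
  aborted <- FALSE
  for (k in seq_len(hyper@kmax)) {
    ad <- adamInit(length(theta))          # Adam moments reset each epoch
    norms <- numeric(hyper@imax)
    nIter <- 0L
    epochSeed <- childSeed(seed, 1000L + k)
    for (i in seq_len(hyper@imax)) {
      fl <- flow; fl@weights <- theta
      ob <- tryCatch(
        alObjective(fl, model, suff, eta, cpen, hyper@batchN,
                    seed = childSeed(epochSeed, i)),
        error = function(e) e)
      if (inherits(ob, "error")) {
        warning("epoch ", k, " aborted at iteration ", i, ": ",
                conditionMessage(ob))
        aborted <- TRUE
        break
      }
      ad <- adamStep(ad, ob$grad, hyper@lr)
      theta <- theta - ad$step
      norms[i] <- ob$normR
      nIter <- i
      if (!is.null(logCon) && (i %% logEvery == 0L || i == 1L)) {
        writeLines(jsonlite::toJSON(list(epoch = k, iter = i,
          loss = ob$loss, entropy = ob$entropy, normR = ob$normR,
          c = cpen), auto_unbox = TRUE, digits = NA), logCon)
      }
    }
    if (nIter == 0L) break                 # nothing usable this epoch
    norms <- norms[seq_len(nIter)]
    flow@weights <- theta
    ## epoch-end bookkeeping: eta update from a fresh batch, convergence test
    s <- sampleFlow(flow, hyper@batchN, seed = childSeed(epochSeed, 900001L))
    cv <- constraintViolation(model, suff, s$z,
                              seed = childSeed(epochSeed, 900002L))
    etaNew <- updateEta(eta, cpen, cv$R)
    ct <- convergenceTest(flow, model, suff, Ntest = hyper@Ntest,
                          reps = hyper@testReps, alpha = alpha,
                          seed = childSeed(epochSeed, 900003L))
    he <- entropyEstimate(flow, entropyN, seed = childSeed(epochSeed, 900004L))
    cNew <- cpen; pRed <- NA_real_
    if (!is.null(normsPrev)) {
      uc <- updateC(cpen, normsPrev, norms, gamma = hyper@gamma,
                    beta = hyper@beta, seed = childSeed(epochSeed, 900005L))
      cNew <- uc$c; pRed <- uc$p
    }
    hist[[k]] <- data.frame(epoch = k, entropy = he$entropy,
                            entropySe = he$se, normR = sqrt(sum(cv$R^2)),
                            minP = min(ct$p), converged = ct$converged,
                            c = cpen, pReduction = pRed,
                            etaNorm = sqrt(sum(etaNew^2)))
    snapshots[[k]] <- theta
    if (verbose)
      message(sprintf(
        "epoch %d: H=%.3f ||R||=%.4f minP=%.3f conv=%s c=%.3g", k,
        he$entropy, sqrt(sum(cv$R^2)), min(ct$p), ct$converged, cpen))
    plateau <- ct$converged && !is.na(lastEntropy) &&
      abs(he$entropy - lastEntropy) < 0.1
    eta <- etaNew; cpen <- cNew; normsPrev <- norms
    lastEntropy <- he$entropy
    if (aborted || plateau) break
  }
  if (length(hist) == 0L)
    stop("epiFit: no epoch completed any iteration", call. = FALSE)
  history <- do.call(rbind, hist)
  convergedEpochs <- history$epoch[history$converged]
  converged <- length(convergedEpochs) > 0L
  bestEpoch <- if (converged) {
    convergedEpochs[which.max(history$entropy[history$converged])]
  } else {
    ## not converged: return the epoch of smallest constraint violation
    history$epoch[which.min(history$normR)]
  }
  bestFlow <- flow
  bestFlow@weights <- snapshots[[bestEpoch]]
  new("EPIResult", bestFlow = bestFlow, bestEpoch = as.integer(bestEpoch),
      converged = converged, history = history, eta = eta, penalty = cpen,
      seed = as.integer(seed),
      config = list(model = model@name, mu = ep@mu, sigma2 = ep@sigma2,
                    innerTrials = ep@innerTrials,
                    hyper = list(c0 = hyper@c0, beta = hyper@beta,
                                 gamma = hyper@gamma, imax = hyper@imax,
                                 kmax = hyper@kmax, batchN = hyper@batchN,
                                 lr = hyper@lr, Ntest = hyper@Ntest,
                                 testReps = hyper@testReps)))
}
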