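## Interrogation of a trained flow: log-density Hessians and sensitivity
## eigendimensions, constrained mode finding with warm-started continuation,
## mode-based sample grouping, and perturbation sweeps along chosen
## directions.

#' Hessian of the flow log density at a point
#'
#' Central finite differences of the analytic log-density gradient
#' (\code{\link{logProbGrad}}), symmetrized. The point must lie strictly
#' inside the support (the support-map derivative diverges on the boundary).
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param z interior parameter point
#' @param h finite-difference step (absolute, per dimension)
#' @return D x D symmetric matrix (1/units^2)
#' @export
logProbHessian <- function(flow, z, h = 1e-4) {
  D <- flow@architecture@dim
  z <- as.numeric(z)
  stopifnot(length(z) == D)
  lo <- flow@support@lower; up <- flow@support@upper
  if (any(z <= lo | z >= up))
    stop("logProbHessian: z must be strictly inside the support box",
         call. = FALSE)
  hv <- rep_len(h, D)
  ## keep stencil points interior
  hv <- pmin(hv, pmax((pmin(up, z + 1) - z) / 2, 1e-9),
             pmax((z - pmax(lo, z - 1)) / 2, 1e-9))
  Zp <- matrix(z, D, D, byrow = TRUE) + diag(hv)
  Zm <- matrix(z, D, D, byrow = TRUE) - diag(hv)
  Gp <- logProbGrad(flow, Zp)
  Gm <- logProbGrad(flow, Zm)
  H <- (Gp - Gm) / (2 * hv)          # row i: d grad / d z_i
  (H + t(H)) / 2
}

#' Sensitivity dimensions of a flow at a point
#'
#' Eigendecomposition of the log-density Hessian with eigenvalues in
#' ascending order: the first eigenvector (most negative eigenvalue) is the
#' sensitivity dimension along which the emergent property deteriorates
#' fastest. Sign degeneracy is fixed by requiring a chosen coordinate of
#' each eigenvector to carry a chosen sign.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param z interior parameter point
#' @param signConvention list(index, sign): coordinate index and required
#'   sign (+1 or -1) of each eigenvector
#' @return a \linkS4class{SensitivityReport}
#' @export
sensitivityDimensions <- function(flow, z,
                                  signConvention = list(index = 1L,
                                                        sign = 1)) {
  H <- logProbHessian(flow, z)
  if (any(!is.finite(H)))
    stop("sensitivityDimensions: non-finite Hessian", call. = FALSE)
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)            # ascending; ties keep index order
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  ix <- signConvention$index; sg <- signConvention$sign
  for (j in seq_len(ncol(vecs))) {
    if (vecs[ix, j] * sg < 0) vecs[, j] <- -vecs[, j]
  }
  new("SensitivityReport", location = as.numeric(z), hessian = H,
      eigenvalues = vals, eigenvectors = vecs,
      signConvention = signConvention)
}

#' Find a (possibly clamped) mode of the flow by gradient ascent
#'
#' Fixed-step gradient ascent on log q over the free coordinates, following
#' a schedule of (steps, learning rate, decay) phases; the learning rate is
#' halved (or multiplied by \code{decay}) every \code{decayEvery} steps
#' within a phase. Clamped coordinates are held exactly at their values.
#' Steps that would leave the support are projected back inside.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param zInit interior starting point (clamped coordinates at their values)
#' @param fixedIndices,fixedValues coordinates to clamp (may be empty)
#' @param schedule list of phases, each \code{list(steps, lr, decay,
#'   decayEvery)}; default mirrors a 500-step 5e-3 phase then 200 steps at
#'   1e-3, decay 0.5 every 100 steps
#' @return list with \code{z} (the mode), \code{logProb}, and \code{path}
#'   log-density trace
#' @export
findMode <- function(flow, zInit, fixedIndices = integer(0),
                     fixedValues = numeric(0),
                     schedule = list(list(steps = 500L, lr = 5e-3,
                                          decay = 0.5, decayEvery = 100L),
                                     list(steps = 200L, lr = 1e-3,
                                          decay = 0.5, decayEvery = 100L))) {
  D <- flow@architecture@dim
  z <- as.numeric(zInit)
  stopifnot(length(z) == D, length(fixedIndices) == length(fixedValues))
  z[fixedIndices] <- fixedValues
  lo <- flow@support@lower; up <- flow@support@upper
  eps <- ifelse(is.finite(up - lo), (up - lo) * 1e-6, 1e-6)
  free <- setdiff(seq_len(D), fixedIndices)
  lp <- logProb(flow, z)
  path <- lp
  for (ph in schedule) {
    lr <- ph$lr
    dec <- if (is.null(ph$decay)) 0.5 else ph$decay
    de <- if (is.null(ph$decayEvery)) 100L else ph$decayEvery
    for (it in seq_len(ph$steps)) {
      g <- logProbGrad(flow, z)[1, ]
      zNew <- z
      zNew[free] <- z[free] + lr * g[free]
      outside <- zNew < lo + eps | zNew > up - eps
      if (any(outside)) {
        zNew <- pmin(pmax(zNew, lo + eps), up - eps)
        zNew[fixedIndices] <- fixedValues
      }
      lpNew <- logProb(flow, zNew)
      if (is.finite(lpNew) && lpNew >= lp) {      # accepted step
        z <- zNew; lp <- lpNew
      }
      path <- c(path, lp)
      if (it %% de == 0L) lr <- lr * dec
    }
  }
  list(z = z, logProb = lp, path = path)
}

#' Warm-started chain of clamped modes along one coordinate
#'
#' The first anchor is initialized from the flow sample (among
#' \code{nInitSamples} draws) whose clamped coordinate is closest to it;
#' each subsequent mode starts from the previous one.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param fixedIndex coordinate to clamp
#' @param anchors ordered clamp values
#' @param seed integer seed for the initialization draw
#' @param nInitSamples draws used to initialize the first anchor
#' @param schedule passed to \code{\link{findMode}} (first anchor); later
#'   anchors use \code{scheduleNext}
#' @param scheduleNext schedule for warm-started anchors (200 steps at 1e-3,
#'   decay 0.5 every 100)
#' @return a \linkS4class{ModeSet}
#' @export
continuationModes <- function(flow, fixedIndex, anchors, seed = 1L,
                              nInitSamples = 500L,
                              schedule = list(list(steps = 500L, lr = 5e-3,
                                                   decay = 0.5,
                                                   decayEvery = 100L)),
                              scheduleNext = list(list(steps = 200L,
                                                       lr = 1e-3,
                                                       decay = 0.5,
                                                       decayEvery = 100L))) {
  s <- sampleFlow(flow, nInitSamples, seed)
  i0 <- which.min(abs(s$z[, fixedIndex] - anchors[1]))
  zCur <- s$z[i0, ]
  modes <- matrix(NA_real_, length(anchors), flow@architecture@dim)
  lps <- numeric(length(anchors))
  for (a in seq_along(anchors)) {
    fm <- findMode(flow, zCur, fixedIndices = fixedIndex,
                   fixedValues = anchors[a],
                   schedule = if (a == 1L) schedule else scheduleNext)
    modes[a, ] <- fm$z
    lps[a] <- fm$logProb
    zCur <- fm$z
  }
  new("ModeSet", fixedIndex = as.integer(fixedIndex),
      anchors = as.numeric(anchors), modes = modes, logDensity = lps)
}

#' Assign samples to their closest mode
#'
#' Euclidean distance in raw parameter units; ties resolve to the
#' lowest-index mode.
#'
#' @param samples n x D matrix of parameter draws
#' @param modes a \linkS4class{ModeSet}
#' @return integer labels (1-based mode indices)
#' @export
groupByMode <- function(samples, modes) {
  M <- modes@modes
  if (nrow(M) == 0L) stop("groupByMode: empty ModeSet", call. = FALSE)
  samples <- asPointMatrix(samples, ncol(M))
  d2 <- outer(rowSums(samples^2), rep(1, nrow(M))) -
    2 * samples %*% t(M) + outer(rep(1, nrow(samples)), rowSums(M^2))
  apply(d2, 1L, which.min)           # which.min takes the first (lowest) tie
}

#' Statistics and log density along a line in parameter space
#'
#' Evaluates \code{z = zStar + delta * v} for each delta: simulated
#' emergent-property statistics (with standard errors over trials) and the
#' flow log density. Out-of-support points are kept in the table and
#' flagged, with NA statistics.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param model a \linkS4class{CircuitModel}
#' @param ep an \linkS4class{EmergentProperty}
#' @param zStar base point; @param v unit direction
#' @param deltas numeric offsets
#' @param trials simulations per point
#' @param seed integer seed
#' @return data.frame with delta, one column per statistic (and its SE),
#'   logProb and inSupport
#' @export
perturbLine <- function(flow, model, ep, zStar, v, deltas, trials = 50L,
                        seed = 1L) {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
    stop("perturbLine: v must be unit norm", call. = FALSE)
  D <- flow@architecture@dim
  lo <- flow@support@lower; up <- flow@support@upper
  Z <- t(vapply(deltas, function(d) zStar + d * v, numeric(D)))
  inSup <- apply(Z, 1L, function(z) all(z > lo & z < up))
  if (any(!inSup))
    warning("perturbLine: ", sum(!inSup), " point(s) outside the support")
  mf <- length(ep@mu)
  stats <- matrix(NA_real_, length(deltas), mf)
  ses <- matrix(NA_real_, length(deltas), mf)
  for (i in seq_along(deltas)) {
    if (!inSup[i]) next
    perTrial <- vapply(seq_len(trials), function(tr)
      circuitStatistics(model, matrix(Z[i, ], 1L), nTrials = 1L,
                        seed = childSeed(seed, (i - 1L) * trials + tr))$f[1, ],
      numeric(mf))
    perTrial <- matrix(perTrial, nrow = mf)
    stats[i, ] <- rowMeans(perTrial)
    ses[i, ] <- apply(perTrial, 1L, sd) / sqrt(trials)
  }
  lp <- rep(NA_real_, length(deltas))
  lp[inSup] <- logProb(flow, Z[inSup, , drop = FALSE])
  out <- data.frame(delta = deltas, stats, ses, logProb = lp,
                    inSupport = inSup)
  names(out)[2:(1 + mf)] <- ep@statNames
  names(out)[(2 + mf):(1 + 2 * mf)] <- paste0(ep@statNames, "SE")
  out
}
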