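## Emergent properties -> sufficient statistics, constraint violations and
## the convergence hypothesis test.

#' Define an emergent property
#'
#' @param statNames labels of the statistics f(x; z)
#' @param mu target means (statistic units)
#' @param sigma2 target variances (> 0, squared units)
#' @param innerTrials simulations averaged per parameter draw
#' @return an \linkS4class{EmergentProperty}
#' @examples
#' emergentProperty(c("real_lambda1", "imag_lambda1"),
#'                  mu = c(0, 2 * pi), sigma2 = c(0.25^2, (pi / 5)^2))
#' @export
emergentProperty <- function(statNames, mu, sigma2, innerTrials = 1L) {
  new("EmergentProperty", statNames = as.character(statNames),
      mu = as.numeric(mu), sigma2 = as.numeric(sigma2),
      innerTrials = as.integer(innerTrials))
}

#' Build the sufficient-statistics description of an emergent property
#'
#' The maximum-entropy problem constrains the expectation of
#' \code{T(z) = c(fbar(z), (fbar(z) - mu)^2)} to \code{muOpt = c(mu, sigma2)},
#' where \code{fbar} averages the statistics over the property's inner trials
#' and the second moments deviate from the FIXED target means, not the batch
#' mean.
#'
#' @param ep an \linkS4class{EmergentProperty}
#' @return a \linkS4class{SufficientStatistics}
#' @export
makeConstraints <- function(ep) {
  validObject(ep)
  new("SufficientStatistics", property = ep, muOpt = c(ep@mu, ep@sigma2))
}

#' Number of scalar constraints (m = 2 * m_f)
#' @param suff a \linkS4class{SufficientStatistics}
#' @export
nConstraints <- function(suff) 2L * length(suff@property@mu)

#' @rdname makeConstraints
#' @param suff a \linkS4class{SufficientStatistics}
#' @export
muOpt <- function(suff) suff@muOpt

## Evaluate T(z) (and, optionally, dT/dz) for a batch of parameter rows.
## Returns list(T = n x m, grad = n x m x D array or NULL, nBad).
suffStatsBatch <- function(model, suff, z, seed, withGrad = FALSE) {
  ep <- suff@property
  st <- circuitStatistics(model, z, nTrials = ep@innerTrials, seed = seed,
                          withGrad = withGrad)
  fbar <- st$f
  mf <- length(ep@mu)
  dev <- sweep(fbar, 2L, ep@mu, "-")
  Tm <- cbind(fbar, dev^2)
  out <- list(T = Tm, grad = NULL,
              nBad = sum(!stats::complete.cases(Tm) | !is.finite(rowSums(Tm))))
  if (withGrad) {
    n <- nrow(z); D <- ncol(z)
    G <- array(0, dim = c(n, 2L * mf, D))
    G[, seq_len(mf), ] <- st$grad
    for (k in seq_len(mf)) G[, mf + k, ] <- 2 * dev[, k] * st$grad[, k, ]
    out$grad <- G
  }
  out
}

#' Monte-Carlo constraint violations of a flow (or a given parameter batch)
#'
#' Estimates \code{R = E[T(z)] - muOpt} from a batch of parameter draws, with
#' per-component standard errors. Parameter rows whose statistics are
#' non-finite are dropped and counted.
#'
#' @param model a \linkS4class{CircuitModel}
#' @param suff a \linkS4class{SufficientStatistics}
#' @param z n x D matrix of parameter draws
#' @param seed integer seed for the inner simulations
#' @return list with \code{R} (length m), \code{se}, \code{n} (rows used) and
#'   \code{nBad} (rows dropped as non-finite)
#' @export
constraintViolation <- function(model, suff, z, seed = 1L) {
  if (nrow(z) < 1L) stop("constraintViolation: empty batch", call. = FALSE)
  ss <- suffStatsBatch(model, suff, z, seed, withGrad = FALSE)
  constraintViolationFromT(ss$T, suff)
}

## From a precomputed T matrix.
constraintViolationFromT <- function(Tm, suff) {
  ok <- is.finite(rowSums(Tm))
  nBad <- sum(!ok)
  if (!any(ok))
    stop("constraintViolation: all samples produced non-finite statistics",
         call. = FALSE)
  Tok <- Tm[ok, , drop = FALSE]
  n <- nrow(Tok)
  R <- colMeans(Tok) - suff@muOpt
  se <- if (n > 1L) apply(Tok, 2L, sd) / sqrt(n) else rep(NA_real_, ncol(Tok))
  list(R = R, se = se, n = n, nBad = nBad)
}

#' Convergence hypothesis test for the emergent-property constraints
#'
#' For each constraint i, \code{reps} independent sample means of the
#' violation R_i are formed from batches of \code{Ntest} flow draws. The
#' two-tailed nonparametric p-value is
#' \code{2 * min(frac(means >= 0), frac(means <= 0))}, clipped to
#' \code{[1/reps, 1]}. The flow has converged when every p-value passes the
#' Bonferroni-adjusted threshold \code{alpha / m}.
#'
#' @param flow a \linkS4class{FlowDistribution}
#' @param model a \linkS4class{CircuitModel}
#' @param ep an \linkS4class{EmergentProperty} (or
#'   \linkS4class{SufficientStatistics})
#' @param Ntest samples per batch (>= 2)
#' @param reps number of sample-mean replicates
#' @param alpha significance level before Bonferroni correction
#' @param seed integer seed
#' @return list with \code{converged}, \code{p} (length m), \code{threshold},
#'   and \code{means} (reps x m matrix of replicate violation means)
#' @export
convergenceTest <- function(flow, model, ep, Ntest, reps = 200L,
                            alpha = 0.05, seed = 1L) {
  stopifnot(Ntest >= 2L)
  suff <- if (is(ep, "SufficientStatistics")) ep else makeConstraints(ep)
  m <- nConstraints(suff)
  ntot <- as.integer(Ntest) * as.integer(reps)
  s <- sampleFlow(flow, ntot, seed = childSeed(seed, 1L))
  ss <- suffStatsBatch(model, suff, s$z, seed = childSeed(seed, 2L))
  dev <- sweep(ss$T, 2L, suff@muOpt, "-")
  ok <- is.finite(rowSums(dev))
  if (!all(ok)) {
    warning(sum(!ok), " non-finite statistic row(s) dropped in convergence",
            " test; effective reps reduced accordingly")
    dev[!ok, ] <- NA_real_
  }
  grp <- rep(seq_len(reps), each = Ntest)
  means <- apply(dev, 2L, function(col) {
    tapply(col, grp, mean, na.rm = TRUE)
  })
  means <- matrix(means, nrow = reps, ncol = m)
  p <- vapply(seq_len(m), function(i) {
    mi <- means[, i]; mi <- mi[is.finite(mi)]
    pv <- 2 * min(mean(mi >= 0), mean(mi <= 0))
    min(max(pv, 1 / length(mi)), 1)
  }, numeric(1))
  thr <- alpha / m
  if (1 / reps >= thr)
    warning("convergenceTest: 1/reps >= alpha/m; the clipped p-value floor ",
            "cannot fall below the Bonferroni threshold, so the test can ",
            "never reject -- increase reps")
  list(converged = all(p >= thr), p = p, threshold = thr, means = means)
}
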