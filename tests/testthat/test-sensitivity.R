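## A flow fitted to a known diagonal Gaussian provides closed-form oracles
## for Hessians, modes and eigen-structure.

gaussFitFlow <- function(varTarget = c(0.01, 1), seed = 21L) {
  fl <- buildFlow(flowArchitecture(dim = length(varTarget),
                                   conditionerWidth = 20L),
                  boxSupport(rep(-Inf, length(varTarget)),
                             rep(Inf, length(varTarget))), seed = seed)
  fitToGaussian(fl, rep(0, length(varTarget)), varTarget, iters = 600L,
                seed = seed + 1L, batchN = 200L)
}

test_that("log-density Hessians are symmetric and match closed forms", {
  fl <- gaussFitFlow(c(0.25, 1))
  H <- logProbHessian(fl, c(0.05, -0.1))
  expect_lt(max(abs(H - t(H))), 1e-6)
  expect_equal(diag(H), c(-1 / 0.25, -1 / 1), tolerance = 0.12)
  ## agreement with second differences of logProb directly
  h <- 1e-3
  num <- matrix(0, 2, 2)
  z0 <- c(0.05, -0.1)
  for (i in 1:2) for (j in 1:2) {
    ei <- numeric(2); ei[i] <- h; ej <- numeric(2); ej[j] <- h
    num[i, j] <- (logProb(fl, z0 + ei + ej) - logProb(fl, z0 + ei - ej) -
                    logProb(fl, z0 - ei + ej) + logProb(fl, z0 - ei - ej)) /
      (4 * h^2)
  }
  expect_equal(H, num, tolerance = 2e-3, ignore_attr = TRUE)
  ## eigen-decomposition reconstruction
  rep_ <- sensitivityDimensions(fl, z0)
  V <- rep_@eigenvectors
  expect_lt(max(abs(H - V %*% diag(rep_@eigenvalues) %*% t(V))), 1e-6)
})

test_that("Hessians error on the boundary and on random points stay symmetric", {
  fl <- smallFlow(2L, lower = c(0, 0), upper = c(1, 1))
  expect_error(logProbHessian(fl, c(0, 0.5)), "inside")
  s <- sampleFlow(fl, 10L, seed = 3L)
  for (i in 1:10) {
    H <- logProbHessian(fl, s$z[i, ])
    expect_lt(max(abs(H - t(H))), 1e-6)
  }
})

test_that("sensitivity dimensions order by eigenvalue and fix signs", {
  fl <- gaussFitFlow(c(0.01, 1))
  rep_ <- sensitivityDimensions(fl, c(0, 0),
                                signConvention = list(index = 1L, sign = 1))
  expect_true(!is.unsorted(rep_@eigenvalues))
  ## most sensitive direction is the low-variance axis, within 5 degrees
  v1 <- rep_@eigenvectors[, 1]
  ang <- acos(min(abs(v1[1]), 1)) * 180 / pi
  expect_lt(ang, 5)
  expect_gte(v1[1], 0)   # sign convention
  repNeg <- sensitivityDimensions(fl, c(0, 0),
                                  signConvention = list(index = 2L,
                                                        sign = -1))
  expect_true(all(repNeg@eigenvectors[2, ] <= 0))
})

test_that("mode finding climbs to the Gaussian mean and respects clamps", {
  fl <- gaussFitFlow(c(0.5, 0.5))
  fm <- findMode(fl, c(1, -1),
                 schedule = list(list(steps = 300L, lr = 5e-2, decay = 0.7,
                                      decayEvery = 100L)))
  expect_lt(max(abs(fm$z)), 0.08)
  expect_true(all(diff(fm$path) >= 0))   # accepted steps never decrease
  ## clamping holds the coordinate exactly
  fmC <- findMode(fl, c(0.75, 0.5), fixedIndices = 1L, fixedValues = 0.75)
  expect_identical(fmC$z[1], 0.75)
})

test_that("warm-started mode continuation tracks clamped conditional modes", {
  ## oracle: a fine grid search over the free coordinate at each anchor
  fl <- smallFlow(2L, lower = c(-3, -3), upper = c(3, 3), jitter = 0.4,
                  seed = 31L)
  anchors <- c(1, 0.5, 0, -0.5, -1)
  ms <- continuationModes(fl, fixedIndex = 1L, anchors = anchors, seed = 5L)
  expect_identical(ms@modes[, 1], anchors)
  grid <- seq(-2.9, 2.9, length.out = 1200L)
  for (i in seq_along(anchors)) {
    lp <- logProb(fl, cbind(anchors[i], grid))
    zOracle <- grid[which.max(lp)]
    expect_lt(abs(ms@modes[i, 2] - zOracle), 0.1)
    expect_gte(ms@logDensity[i], max(lp) - 0.05)
  }
  ## single anchor
  ms1 <- continuationModes(fl, 1L, anchors = 0.25, seed = 6L)
  expect_identical(nrow(ms1@modes), 1L)
})

test_that("samples group to their closest mode with a stable tie-break", {
  ms <- new("ModeSet", fixedIndex = 1L, anchors = c(-1, 1),
            modes = rbind(c(-1, 0), c(1, 0)), logDensity = c(0, 0))
  samples <- rbind(c(-1.2, 0.3), c(0.9, -0.1), c(0, 0))
  lab <- groupByMode(samples, ms)
  expect_identical(lab, c(1L, 2L, 1L))   # midpoint ties to the lowest index
  ## one mode: everything labeled 1; exact hits label themselves
  ms1 <- new("ModeSet", fixedIndex = 1L, anchors = 0,
             modes = matrix(c(0, 0), 1), logDensity = 0)
  expect_true(all(groupByMode(samples, ms1) == 1L))
  expect_identical(groupByMode(matrix(c(1, 0), 1), ms), 2L)
  ## idempotent and order-invariant
  perm <- c(3, 1, 2)
  expect_identical(groupByMode(samples[perm, ], ms), lab[perm])
})

test_that("perturbation sweeps are symmetric for Gaussian flows and flag support exits", {
  fl <- gaussFitFlow(c(0.5, 0.5))
  mod <- identityModel(2L)
  ep <- emergentProperty(c("z1", "z2"), mu = c(0, 0), sigma2 = c(1, 1))
  fm <- findMode(fl, c(0.3, 0.3))
  rep_ <- sensitivityDimensions(fl, fm$z)
  v <- rep_@eigenvectors[, 1]
  deltas <- seq(-0.6, 0.6, by = 0.2)
  tab <- perturbLine(fl, mod, ep, fm$z, v, deltas, trials = 10L, seed = 3L)
  expect_identical(nrow(tab), length(deltas))
  lp <- tab$logProb
  asym <- abs(lp - rev(lp))
  expect_lt(max(asym), 0.12)
  ## delta = 0 row reproduces the base point within Monte-Carlo error
  mid <- which.min(abs(deltas))
  expect_lt(abs(tab$z1[mid] - fm$z[1]), 3 * tab$z1SE[mid] + 1e-9)
  ## non-unit directions are rejected; support exits are flagged
  expect_error(perturbLine(fl, mod, ep, fm$z, c(1, 1), deltas), "unit")
  flb <- smallFlow(2L, lower = c(0, 0), upper = c(1, 1))
  expect_warning(
    tb <- perturbLine(flb, mod, ep, c(0.5, 0.5), c(1, 0),
                      deltas = c(0, 0.7), trials = 2L, seed = 1L),
    "outside")
  expect_false(tb$inSupport[2])
})
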