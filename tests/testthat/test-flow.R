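test_that("build_flow validates configuration and counts parameters", {
  arch <- flowArchitecture(dim = 4L, conditionerWidth = 50L)
  expect_error(buildFlow(arch, boxSupport(c(0, 0), c(1, 1)), 1L),
               "configuration error")
  expect_error(boxSupport(c(0, 2), c(1, 1)), "degenerate")
  fl1 <- buildFlow(arch, boxSupport(rep(-10, 4), rep(10, 4)), seed = 1L)
  fl2 <- buildFlow(arch, boxSupport(rep(-10, 4), rep(10, 4)), seed = 9L)
  expect_identical(length(fl1@weights), length(fl2@weights))
  expect_identical(length(fl1@weights), nFlowParams(arch))
})

test_that("freshly built flows are the base Gaussian pushed into the box", {
  ## unbounded support: identity transform, standard-normal log density
  fl <- buildFlow(flowArchitecture(dim = 4L, conditionerWidth = 10L),
                  boxSupport(rep(-Inf, 4), rep(Inf, 4)), seed = 2L)
  z <- matrix(rnorm(40), 10, 4)
  expect_equal(logProb(fl, z), epinfer:::rowLogDnorm(z), tolerance = 1e-12)
  s <- sampleFlow(fl, 10000L, seed = 5L)
  expect_lt(max(abs(colMeans(s$z))), 4 / sqrt(10000))

  ## unit-box support: all samples strictly inside
  flb <- buildFlow(flowArchitecture(dim = 2L, conditionerWidth = 10L),
                   boxSupport(c(0, 0), c(1, 1)), seed = 3L)
  sb <- sampleFlow(flb, 10000L, seed = 6L)
  expect_true(all(sb$z > 0 & sb$z < 1))
})

test_that("sampling, inversion and log densities are mutually consistent", {
  for (fl in list(smallFlow(3L),
                  smallFlow(2L, lower = c(0, -Inf), upper = c(Inf, 5)),
                  smallFlow(5L, lower = rep(-1, 5), upper = rep(1, 5),
                            stages = 4L))) {
    s <- sampleFlow(fl, 1000L, seed = 7L)
    inv <- epinfer:::flowInverse(fl, s$z)
    expect_lt(max(abs(inv$z0 - s$z0) / (abs(s$z0) + 1)), 1e-5)
    expect_lt(max(abs(logProb(fl, s$z) - s$logDensity)), 1e-5)
  }
})

test_that("empty batches are returned for n = 0", {
  fl <- smallFlow(2L)
  s <- sampleFlow(fl, 0L, seed = 1L)
  expect_identical(nrow(s$z), 0L)
  expect_length(s$logDensity, 0L)
})

test_that("change-of-variables log density matches a numerical Jacobian", {
  fl <- smallFlow(3L)
  s <- sampleFlow(fl, 8L, seed = 11L)
  for (i in 1:8) {
    ld <- epinfer:::flowForward(fl, s$z0[i, , drop = FALSE])$logdet
    expect_equal(ld, numericalLogDet(fl, s$z0[i, ]), tolerance = 1e-4)
  }
})

test_that("log densities integrate correctly in one dimension", {
  ## histogram of samples vs exp(log_prob) on a grid, total variation < 0.02
  fl <- smallFlow(1L, lower = -3, upper = 3, jitter = 0.5)
  s <- sampleFlow(fl, 100000L, seed = 13L)
  breaks <- seq(-3, 3, length.out = 61L)
  hcount <- hist(s$z[, 1], breaks = breaks, plot = FALSE)$counts
  mid <- (breaks[-1] + breaks[-61]) / 2
  dens <- exp(logProb(fl, matrix(mid, ncol = 1)))
  dens <- dens / sum(dens)
  emp <- hcount / sum(hcount)
  expect_lt(sum(abs(dens - emp)) / 2, 0.02)
})

test_that("out-of-support points give -Inf or an error per the flag", {
  fl <- smallFlow(2L, lower = c(0, 0), upper = c(1, 1))
  bad <- matrix(c(1.5, 0.5), 1)
  expect_identical(logProb(fl, bad), -Inf)
  expect_error(logProb(fl, bad, outOfSupport = "error"), "outside")
})

test_that("analytic gradients of log q match finite differences", {
  fl <- smallFlow(3L)
  s <- sampleFlow(fl, 6L, seed = 17L)
  g <- logProbGrad(fl, s$z)
  h <- 1e-6
  for (i in 1:6) for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    fd <- (logProb(fl, s$z[i, ] + e) - logProb(fl, s$z[i, ] - e)) / (2 * h)
    expect_equal(g[i, j], fd, tolerance = 1e-4)
  }
})

test_that("weight gradients through the forward pass match finite differences", {
  fl <- smallFlow(2L, width = 6L, stages = 2L)
  Z0 <- epinfer:::seededNormals(5L, 2L, 19L)
  Wz <- epinfer:::seededNormals(5L, 2L, 23L)
  vv <- epinfer:::seededNormals(5L, 1L, 29L)[, 1]
  fw <- epinfer:::flowForward(fl, Z0, keepCache = TRUE)
  g <- epinfer:::flowBackward(fl, fw$cache, Wz, vv)
  lossAt <- function(th) {
    f2 <- fl; f2@weights <- th
    r <- epinfer:::flowForward(f2, Z0)
    sum(Wz * r$z) + sum(vv * r$logdet)
  }
  idx <- epinfer:::withSeed(31L, sample(length(fl@weights), 20L))
  for (k in idx) {
    tp <- fl@weights; tp[k] <- tp[k] + 1e-6
    tm <- fl@weights; tm[k] <- tm[k] - 1e-6
    fd <- (lossAt(tp) - lossAt(tm)) / 2e-6
    expect_equal(g[k], fd, tolerance = 1e-3)
  }
})

test_that("fitting to a Gaussian recovers its moments and entropy", {
  fl <- buildFlow(flowArchitecture(dim = 2L, conditionerWidth = 20L),
                  boxSupport(rep(-Inf, 2), rep(Inf, 2)), seed = 4L)
  fit <- fitToGaussian(fl, c(0, 0), c(1, 1), iters = 400L, seed = 5L,
                       batchN = 200L)
  s <- sampleFlow(fit, 4000L, seed = 6L)
  expect_lt(max(abs(colMeans(s$z))), 3 * 1 / sqrt(4000) * 1.5)
  he <- entropyEstimate(fit, 4000L, seed = 7L)
  expect_equal(he$entropy, log(2 * pi * exp(1)), tolerance = 0.1)

  ## bounded, off-center target (conductance-style support)
  flb <- buildFlow(flowArchitecture(dim = 2L, conditionerWidth = 20L),
                   boxSupport(c(4, 0.01), c(8, 4)), seed = 8L)
  fitb <- fitToGaussian(flb, c(6, 2), c(0.25, 0.25), iters = 500L,
                        seed = 9L, batchN = 200L)
  sb <- sampleFlow(fitb, 2000L, seed = 10L)
  expect_true(all(sb$z[, 1] > 4 & sb$z[, 1] < 8))
  expect_lt(max(abs(colMeans(sb$z) - c(6, 2))), 0.2)
  expect_error(fitToGaussian(flb, c(9, 2), c(1, 1)), "inside the support")
})

test_that("entropy estimates scale as 1/sqrt(n) and match closed forms", {
  fl <- buildFlow(flowArchitecture(dim = 3L, conditionerWidth = 10L),
                  boxSupport(rep(-Inf, 3), rep(Inf, 3)), seed = 12L)
  he <- entropyEstimate(fl, 5000L, seed = 1L)
  expect_lt(abs(he$entropy - 1.5 * log(2 * pi * exp(1))), 3 * he$se)
  se1 <- entropyEstimate(fl, 10000L, seed = 2L)$se
  se2 <- entropyEstimate(fl, 40000L, seed = 3L)$se
  expect_lt(abs(se2 / se1 - 0.5), 0.2 * 0.5)
})

test_that("flows serialize to JSON and reload exactly", {
  fl <- smallFlow(3L)
  path <- tempfile(fileext = ".json")
  saveFlow(fl, path)
  fl2 <- loadFlow(path)
  z <- sampleFlow(fl, 50L, seed = 3L)$z
  expect_equal(logProb(fl2, z), logProb(fl, z), tolerance = 1e-12)
  s1 <- sampleFlow(fl, 20L, seed = 8L)
  s2 <- sampleFlow(fl2, 20L, seed = 8L)
  expect_identical(s1$z, s2$z)
})

test_that("identical seeds give identical samples", {
  fl <- smallFlow(2L)
  expect_identical(sampleFlow(fl, 100L, seed = 42L)$z,
                   sampleFlow(fl, 100L, seed = 42L)$z)
})
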