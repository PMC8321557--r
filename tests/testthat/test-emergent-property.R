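test_that("constraint vectors stack means then variances", {
  suff <- makeConstraints(lds2dOscillationProperty())
  expect_equal(muOpt(suff), c(0, 2 * pi, 0.25^2, (pi / 5)^2))
  expect_identical(nConstraints(suff), 4L)

  suffR <- makeConstraints(rnnStableAmplificationProperty())
  expect_equal(muOpt(suffR), c(0.5, 1.5, 0.25^2, 0.25^2))

  ## a single statistic gives m = 2
  suff1 <- makeConstraints(emergentProperty("f", 0.55, 0.025^2))
  expect_identical(nConstraints(suff1), 2L)

  expect_error(emergentProperty("f", 0, 0), "variances")
})

test_that("second moments deviate from the fixed target mean, not the batch mean", {
  ep <- emergentProperty(c("a", "b"), mu = c(1, -1), sigma2 = c(1, 1))
  suff <- makeConstraints(ep)
  mod <- identityModel(2L)
  z <- cbind(c(2, 2), c(0, 0))         # batch mean (2, 0), target (1, -1)
  ss <- epinfer:::suffStatsBatch(mod, suff, z, seed = 1L)
  expect_equal(ss$T[1, ], c(2, 0, (2 - 1)^2, (0 + 1)^2))
})

test_that("constraint violations are exact on constructed batches", {
  ep <- emergentProperty(c("a", "b"), mu = c(0, 1), sigma2 = c(1, 4))
  suff <- makeConstraints(ep)
  mod <- identityModel(2L)
  ## batch matching mu exactly with spread exactly sigma2 -> R = 0
  a <- c(-1, 1); b <- c(-1, 3)         # means (0,1), E[(x-mu)^2] = (1,4)
  cv <- constraintViolation(mod, suff, cbind(a, b), seed = 1L)
  expect_equal(cv$R, setNames(rep(0, 4), NULL), ignore_attr = TRUE)

  ## single-sample batch: R = T(z1) - muOpt
  z1 <- matrix(c(0.5, 2), 1)
  cv1 <- constraintViolation(mod, suff, z1, seed = 1L)
  expect_equal(unname(cv1$R), c(0.5, 2, 0.25, 1) - muOpt(suff))
})

test_that("violations follow Gaussian moment algebra on synthetic statistics", {
  ## f ~ N(muStar, sdStar^2): E[R] = (muStar - mu, sdStar^2 + (muStar-mu)^2 - sigma2)
  mu <- 1; sigma2 <- 0.5; muStar <- 1.3; sdStar <- 0.9
  ep <- emergentProperty("f", mu, sigma2)
  suff <- makeConstraints(ep)
  mod <- identityModel(1L)
  z <- matrix(epinfer:::withSeed(5L, rnorm(1e5, muStar, sdStar)), ncol = 1)
  cv <- constraintViolation(mod, suff, z, seed = 1L)
  expected <- c(muStar - mu, sdStar^2 + (muStar - mu)^2 - sigma2)
  expect_lt(max(abs(cv$R - expected) / cv$se), 3.5)
})

test_that("constraint violation estimates are unbiased across repeated batches", {
  ep <- emergentProperty("f", 0, 1)
  suff <- makeConstraints(ep)
  mod <- identityModel(1L)
  Rs <- vapply(1:300, function(k) {
    z <- matrix(epinfer:::withSeed(k, rnorm(50)), ncol = 1)
    constraintViolation(mod, suff, z, seed = 1L)$R
  }, numeric(2))
  bias <- rowMeans(Rs)
  se <- apply(Rs, 1, sd) / sqrt(300)
  expect_lt(max(abs(bias) / se), 3)
})

test_that("non-finite statistics are dropped and counted", {
  ep <- emergentProperty("f", 0, 1)
  suff <- makeConstraints(ep)
  Tm <- matrix(c(1, NaN, -1, 2), ncol = 2)  # m = 2 columns
  cv <- epinfer:::constraintViolationFromT(matrix(c(1, NaN, 0.5, 1), 2, 2),
                                           suff)
  expect_identical(cv$nBad, 1L)
  expect_identical(cv$n, 1L)
  expect_error(epinfer:::constraintViolationFromT(
    matrix(NaN, 2, 2), suff), "non-finite")
})

test_that("convergence test applies the Bonferroni threshold", {
  fl <- smallFlow(2L, lower = rep(-5, 2), upper = rep(5, 2), jitter = 0)
  ep <- emergentProperty(c("z1", "z2"), mu = c(0, 0), sigma2 = c(1, 1))
  ct <- convergenceTest(fl, identityModel(2L), ep, Ntest = 20L, reps = 100L,
                        alpha = 0.05, seed = 1L)
  expect_equal(ct$threshold, 0.05 / 4)
  expect_length(ct$p, 4L)
})

test_that("convergence test accepts calibrated generators and rejects biased ones", {
  ## flow fitted to N(0, I) against the matching property: mostly accepted
  fl0 <- buildFlow(flowArchitecture(dim = 2L, conditionerWidth = 10L),
                   boxSupport(rep(-Inf, 2), rep(Inf, 2)), seed = 2L)
  epMatch <- emergentProperty(c("z1", "z2"), mu = c(0, 0), sigma2 = c(1, 1))
  mod <- identityModel(2L)
  acc <- vapply(1:50, function(k)
    convergenceTest(fl0, mod, epMatch, Ntest = 100L, reps = 100L,
                    seed = k)$converged, logical(1))
  expect_gte(mean(acc), 0.9)

  ## mean offset of 0.5 sd at Ntest = 100: overwhelmingly rejected
  epOff <- emergentProperty(c("z1", "z2"), mu = c(0.5, 0), sigma2 = c(1, 1))
  rej <- vapply(1:50, function(k)
    !convergenceTest(fl0, mod, epOff, Ntest = 100L, reps = 100L,
                     seed = k)$converged, logical(1))
  expect_gte(mean(rej), 0.95)
})
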