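test_that("the noiseless V1 circuit settles onto its fixed point", {
  mod <- v1Model()
  xs <- v1SteadyState(mod)
  resid <- xs - epinfer:::relu(as.numeric(mod@W %*% xs) +
                                 epinfer:::v1Input(mod))^2
  expect_lt(max(abs(resid)), 1e-3)
  ## near-zero noise: sE below 0.1 Hz
  st <- circuitStatistics(mod, matrix(1e-8, 1, 4), nTrials = 3L, seed = 1L)
  expect_lt(st$f[1, 1], 0.1)
})

test_that("simulations are seed-reproducible and flag runaway trials", {
  mod <- v1Model()
  a <- v1Simulate(c(0.05, 0.05, 0.2, 0.2), trials = 4L, seed = 5L)
  b <- v1Simulate(c(0.05, 0.05, 0.2, 0.2), trials = 4L, seed = 5L)
  expect_identical(as.numeric(a), as.numeric(b))
  ## large sigma_E drives the supralinear runaway; trials are flagged
  bad <- v1Simulate(c(0.45, 0.3, 0.2, 0.2), trials = 6L, seed = 2L)
  expect_true(any(attr(bad, "blown")))
})

test_that("sE measures the steady-state window standard deviation", {
  ## constant trace
  expect_equal(v1sE(rep(10, 200)), 0)
  ## sinusoid of amplitude 1 about 10 Hz: sd ~ sqrt(1/2)
  tt <- (1:200) * 0.5 / 1000
  x <- 10 + sin(2 * pi * 200 * tt)
  expect_equal(v1sE(x), sqrt(0.5), tolerance = 0.05)
  expect_error(v1sE(rep(1, 100), dt = 0.5), "100 ms")
})

test_that("input noise increases excitatory variability", {
  mod <- v1Model()
  z1 <- matrix(c(0.02, 0.02, 0.1, 0.1), 1)
  z2 <- 2 * z1
  f1 <- circuitStatistics(mod, z1, nTrials = 100L, seed = 9L)$f[1, 1]
  f2 <- circuitStatistics(mod, z2, nTrials = 100L, seed = 9L)$f[1, 1]
  expect_gt(f2, f1)   # paired by common noise
})

test_that("the Lyapunov oracle matches simulated linearized covariance", {
  mod <- v1Model()
  xs <- v1SteadyState(mod)
  z <- c(0.05, 0.04, 0.08, 0.06)
  L <- v1LyapunovOracle(mod, z, xs)
  expect_lt(max(abs(L - t(L))), 1e-8)
  ## simulate the linearized white-noise system tau dv = -S v dt + noise
  vStar <- as.numeric(mod@W %*% xs) + epinfer:::v1Input(mod)
  S <- diag(4) - mod@W %*% diag(2 * epinfer:::relu(vStar))
  sigT <- z * sqrt(1 + mod@tau / mod@tauNoise)
  dt <- 0.02; nT <- 4e5
  v <- rep(0, 4)
  acc <- matrix(0, 4, 4); xi <- epinfer:::seededNormals(nT, 4L, 3L)
  sq <- sqrt(2 * dt)
  for (t in seq_len(nT)) {
    v <- v - dt * as.numeric(S %*% v) + sq * sigT * xi[t, ]
    if (t > 1000) acc <- acc + tcrossprod(v)
  }
  emp <- acc / (nT - 1000)
  expect_lt(max(abs(emp - L)), 0.1 * max(abs(L)) + 3 * max(abs(L)) / sqrt(nT / 50))

  ## W = 0: S = I, oracle is diagonal with entries sigmaTilde^2
  mod0 <- mod; mod0@W <- matrix(0, 4, 4)
  L0 <- v1LyapunovOracle(mod0, z, xStar = v1SteadyState(mod0))
  expect_equal(L0, diag(sigT^2), tolerance = 1e-10)
})

test_that("only the P population responds paradoxically", {
  expect_false(v1ParadoxicalTest("E")$paradoxical)
  expect_true(v1ParadoxicalTest("P")$paradoxical)
  expect_false(v1ParadoxicalTest("S")$paradoxical)
  expect_false(v1ParadoxicalTest("V")$paradoxical)
  ## without recurrence no population is paradoxical
  mod0 <- v1Model(); mod0@W <- matrix(0, 4, 4)
  for (p in c("E", "P", "S", "V"))
    expect_false(v1ParadoxicalTest(p, model = mod0)$paradoxical)
})
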