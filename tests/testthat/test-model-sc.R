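test_that("trial inputs sum the printed components", {
  expect_equal(unname(scInput(0.5, "Pro", "Left")),
               c(1.85, 0.75, 1.85, 0.75))
  expect_equal(unname(scInput(1.3, "Anti", "Left")), c(2.0, 1.5, 1.5, 1.0))
  expect_equal(unname(scInput(1.7, "Pro", "Left")), c(1.5, 1.0, 1.5, 1.0))
  expect_error(scInput(2.0, "Pro", "Left"), "outside")
})

test_that("simulated activities respect the response bounds and silencing", {
  z <- c(1, 0.5, -0.5, -0.3)
  tr <- scSimulate(z, "Pro", "Left", trials = 3L, seed = 4L)
  expect_true(all(tr >= 0 & tr <= 1))
  ## gamma = 0 equals baseline bit-exactly under the same seed
  tr0 <- scSimulate(z, "Pro", "Left", gamma = 0, trials = 3L, seed = 4L)
  expect_identical(as.numeric(tr), as.numeric(tr0))
  ## gamma = 1 zeroes activity throughout the delay window
  trS <- scSimulate(z, "Anti", "Left", gamma = 1, trials = 2L, seed = 4L)
  tGrid <- seq_len(dim(trS)[3]) * 0.024
  idx <- which(tGrid > 0.8 & tGrid < 1.2)
  expect_equal(max(abs(trS[, , idx])), 0)
})

test_that("soft decisions saturate, tie at one half, and average correctly", {
  ## saturated correct Pro trial
  x <- matrix(c(1, 0.2, 0, 0.2), 1)   # LP >> RP
  expect_equal(scAccuracy(x, "Pro")$accuracy, 1, tolerance = 1e-10)
  expect_equal(scAccuracy(x, "Anti")$accuracy, 0, tolerance = 1e-10)
  ## tie
  xt <- matrix(c(0.5, 0.1, 0.5, 0.1), 1)
  expect_equal(scAccuracy(xt, "Pro")$accuracy, 0.5)
  ## k correct + k incorrect saturated trials -> 0.5
  xb <- rbind(matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE),
              matrix(c(0, 0, 1, 0), 4, 4, byrow = TRUE))
  expect_equal(scAccuracy(xb, "Pro")$accuracy, 0.5, tolerance = 1e-3)
})

test_that("connectivity eigenvalues are the printed linear map of parameters", {
  ## sW-only connectivity is the identity with a flat spectrum
  expect_equal(unname(scConnectivityEigvals(c(1, 0, 0, 0))), rep(1, 4))
  expect_equal(scConnectivity(c(1, 0, 0, 0)), diag(4), ignore_attr = TRUE)
  ## eigenvalues of W(z) match the linear map as multisets
  for (k in 1:50) {
    z <- epinfer:::withSeed(k, runif(4, -5, 5))
    lam <- scConnectivityEigvals(z)
    ev <- eigen(scConnectivity(z), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lt(max(abs(sort(lam) - sort(ev))), 1e-10)
  }
  ## round trip z -> lambda -> z through A
  A <- epinfer:::scEigModeBasis()
  z <- c(0.3, -1.2, 2.2, 0.7)
  expect_equal(as.numeric(A %*% scConnectivityEigvals(z)), z,
               tolerance = 1e-12)
})

test_that("eigenmode perturbation vectors are unit, orthogonal and selective", {
  vAll <- scEigmodeVector("all")
  expect_equal(vAll, c(1, 1, 1, 1) / 2, ignore_attr = TRUE)
  modes <- c("all", "side", "task", "diag")
  V <- sapply(modes, scEigmodeVector)
  expect_equal(crossprod(V), diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  ## perturbing along v_task changes only lambda_task
  z <- c(0.5, -0.2, 1.1, -2)
  for (m in modes) {
    dLam <- scConnectivityEigvals(z + 0.3 * scEigmodeVector(m)) -
      scConnectivityEigvals(z)
    expect_lt(max(abs(dLam[setdiff(modes, m)])), 1e-10)
    expect_gt(abs(dLam[m]), 0.1)
  }
})

test_that("task statistics respond to connectivity and are seed-stable", {
  mod <- scModel()
  st <- circuitStatistics(mod, rbind(c(0, 0, 0, 0), c(2, 1, -2, -1)),
                          nTrials = 40L, seed = 6L)
  expect_true(all(st$f >= 0 & st$f <= 1))
  st2 <- circuitStatistics(mod, rbind(c(0, 0, 0, 0), c(2, 1, -2, -1)),
                           nTrials = 40L, seed = 6L)
  expect_identical(st$f, st2$f)
})
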