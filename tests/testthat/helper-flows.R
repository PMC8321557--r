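## Shared fixtures: small flows with randomized weights, built in code.

smallFlow <- function(dim = 3L, lower = rep(-2, dim), upper = rep(2, dim),
                      width = 8L, stages = 3L, seed = 3L, jitter = 0.3) {
  fl <- buildFlow(flowArchitecture(nCouplingStages = stages,
                                   conditionerDepth = 2L,
                                   conditionerWidth = width, dim = dim),
                  boxSupport(lower, upper), seed = seed)
  if (jitter > 0)
    fl@weights <- fl@weights +
      epinfer:::withSeed(seed + 1L, rnorm(length(fl@weights), sd = jitter))
  fl
}

## central finite-difference log-det-Jacobian of the forward map at z0
numericalLogDet <- function(fl, z0, h = 1e-5) {
  D <- length(z0)
  J <- matrix(0, D, D)
  for (j in seq_len(D)) {
    e <- numeric(D); e[j] <- h
    zp <- epinfer:::flowForward(fl, matrix(z0 + e, 1))$z
    zm <- epinfer:::flowForward(fl, matrix(z0 - e, 1))$z
    J[, j] <- (zp - zm) / (2 * h)
  }
  as.numeric(determinant(J)$modulus)
}
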