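# epinfer — Emergent Property Inference for neural-circuit models

Theoretical neuroscience builds mechanistic circuit models whose parameters
z produce activity x through differential-equation simulators with
intractable likelihoods. The scientific question is usually inverse: *which
parameter combinations make the circuit compute?* `epinfer` answers it by
learning the **maximum-entropy distribution over parameters that produces a
prescribed emergent property** — first- and second-moment constraints on
statistics f(x; z) of the simulated activity:

    E[f(x;z)] = mu,   Var[f(x;z)] = sigma^2
    q*(z) = argmax H(q)  subject to those constraints.

The distribution is represented by a real NVP normalizing flow (affine
coupling stacks with exact log-densities) mapped onto the parameter box,
and trained by augmented-Lagrangian constrained stochastic optimization:
epochs of Adam iterations on `-H(q) + eta'R + (c/2)||R||^2`, multiplier and
penalty updates between epochs, and a nonparametric hypothesis test of
constraint satisfaction as the convergence criterion. Because the learned
distribution has exact densities, gradients and Hessians, it can be
interrogated directly: Hessian eigenvectors quantify which parameter
combinations the emergent property is most sensitive to, clamped modes
trace degenerate ridges, and perturbation sweeps probe what happens to the
computation away from a mode.

Five differentiable circuit models ship with the package:

| model      | parameters z                            | emergent property             |
|------------|------------------------------------------|-------------------------------|
| `lds2d`    | 2x2 dynamics matrix entries              | 1 Hz oscillation band         |
| `rnn`      | rank-2 factors U1, U2, V1, V2 (4N dims)  | stable amplification          |
| `stg`      | g_el, g_synA conductances (nS)           | intermediate hub frequency    |
| `v1`       | input-noise scales per population        | E-population variability s_E  |
| `sc`       | sW, vW, hW, dW connectivity              | Pro/Anti task accuracy        |

## Worked example

Infer the distribution of 2-D linear systems that oscillate near 1 Hz
(real part of the primary eigenvalue 0 +- 0.25, imaginary part
2*pi +- pi/5):

```r
library(epinfer)
model <- lds2dModel()
ep    <- lds2dOscillationProperty()
hyper <- alHyperparams(c0 = 1, beta = 4, imax = 400L, kmax = 22L,
                       batchN = 1000L, Ntest = 100L)
fit <- epiFit(model, ep, hyper = hyper, seed = 1L,
              gaussInitIters = 1500L, sdInit = 4)
fit
s <- sampleFlow(fit@bestFlow, 1000L, seed = 11L)
f <- lds2dStatistics(s$z)
mean(f[, 2]) / (2 * pi)              # predictive oscillation frequency (Hz)
mean(s$z[, 2] > 0 & s$z[, 3] < 0)    # fraction in the a12 > 0 > a21 lobe
```

A run of this configuration prints (seed 1):

```
EPIResult: converged | best epoch 19 of 19
  entropy 6.599 nats, ||R|| = 0.0757, min p = 0.07, c = 4
[1] 0.9945019
[1] 0.451
```

so the inferred distribution oscillates at 0.9945 Hz on average (the
constrained value is 1 Hz), and both symmetric lobes of the distribution —
`a12 > 0 > a21` and its mirror image — carry about half the mass, the
degeneracy the emergent property leaves open. `sensitivityDimensions`,
`findMode`, `continuationModes`, `groupByMode` and `perturbLine` then
interrogate the fitted flow; `inst/scripts/epi` exposes `fit`, `analyze`,
`simulate` and `sample` verbs over YAML run configurations.

The methods vignette (`vignettes/epi-methods.Rmd`) documents the model
equations, optimizer behavior, numerical choices, and the reduced problem
sizes the test suite runs at.

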