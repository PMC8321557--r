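---
title: "Emergent property inference: models, optimization and design choices"
author: "epinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent property inference: models, optimization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

A mechanistic circuit model maps parameters $z$ to activity $x$ through a
(usually stochastic) simulator. An *emergent property* quantifies a
computation of interest as first- and second-moment constraints on a vector
of activity statistics $f(x;z)$:

$$\mathbb{E}_{z,x}[f(x;z)] = \mu, \qquad \mathrm{Var}_{z,x}[f(x;z)] = \sigma^2.$$

`epinfer` learns the *maximum-entropy* distribution $q_\theta(z)$ over
parameters, within a normalizing-flow family, whose predictive moments match
these targets. The result is an exponential-family distribution given in its
mean parameterization; because the backward mapping from mean to natural
parameters is intractable, the distribution is found by constrained
stochastic optimization rather than in closed form.

The sufficient-statistics vector stacks the trial-averaged statistics and
their squared deviations from the *fixed* targets,
$T(z) = [\bar f(z);\ (\bar f(z)-\mu)^2]$, with constraint values
$\mu_{\mathrm{opt}} = [\mu; \sigma^2]$; the optimizer drives
$R(\theta)=\mathbb{E}_{q_\theta}[T(z)]-\mu_{\mathrm{opt}}$ to zero while
maximizing entropy.

# The flow family

$q_\theta$ is a real NVP coupling stack: a standard-normal base variable is
passed through affine coupling stages whose shift and log-scale are produced
by tanh multilayer perceptrons conditioned on the complementary coordinate
half, with a permutation between stages, and finally through an elementwise
support map onto the parameter box. Jacobians are triangular, so sampling,
exact log-densities, gradients and Hessians are all cheap. Specifics:

* **Support map.** Two-sided dimensions use a scaled logistic
  $z = l + (u-l)\,\mathrm{sigmoid}(y)$; half-open dimensions use softplus;
  unbounded dimensions pass through. Exact log-Jacobians are accumulated
  alongside.
* **Coupling masks.** The first half (size $\lceil D/2\rceil$; odd $D$
  assigns the extra coordinate there) conditions the second half on odd
  stages and vice versa on even stages. "Glow" permutations are fixed
  random permutations drawn once from the build seed; `fixed-swap` swaps
  the halves.
* **Log-scale saturation.** Coupling log-scales pass through
  $5\tanh(s/5)$, which bounds them to $(-5,5)$ smoothly. A hard clamp
  would zero gradients at the bound and break the finite-difference
  agreement checks the package tests enforce.
* **Initialization.** Hidden conditioner weights are Gaussian with
  $1/\sqrt{\text{fan-in}}$ scale; output layers start at zero, so a fresh
  flow *is* its base Gaussian pushed into the box. $D=1$ flows use a single
  global affine stage, since coupling needs two coordinates.
* **Conditioner activation** is tanh throughout (the flows here are small
  and tanh keeps the inverse pass smooth); this choice is recorded in every
  run record via the frozen configuration.

Gradients of the training objective with respect to the weights, and of the
log density with respect to $z$, are computed by hand-written batched
reverse-mode differentiation through the coupling stack (forward pass for
the weight gradient, inverse pass for the input gradient). Both paths are
validated against central finite differences in the test suite, and the
log-density Hessian used by the sensitivity toolbox is a central difference
of the analytic input gradient.

# Augmented-Lagrangian optimization

The objective
$L(\theta) = -H(q_\theta) + \eta^\top R(\theta) + \tfrac{c}{2}\lVert R(\theta)\rVert^2$
is minimized in epochs of Adam iterations (learning rate $10^{-3}$, moments
reset at every epoch boundary). The entropy gradient uses the
reparameterization trick, which reduces to the gradient of the accumulated
log-determinant. The penalty gradient multiplies constraint averages over
two independent half-batches (first vs second half of each iteration
batch), an unbiased estimator of the product-of-expectations structure of
$\nabla\lVert R\rVert^2$.

After each epoch: $\eta \leftarrow \eta + c\,\hat R$ from a fresh batch;
$c$ grows by $\beta$ with probability $1-p$, where $p$ is a one-sided
Welch comparison of the epoch's per-iteration $\lVert\hat R\rVert$ samples
against $\gamma = 0.25$ times the previous epoch's (the choice of test and
of per-epoch sample collection are package decisions; the per-epoch $p$ is
logged). Convergence is declared by a two-tailed nonparametric sign test:
for each constraint, 200 replicate means over `Ntest` fresh samples;
$p_i = 2\min(\widehat{\Pr}[\bar R_i \ge 0], \widehat{\Pr}[\bar R_i \le 0])$
clipped to $[1/\text{reps}, 1]$, accepted when all $p_i \ge \alpha/m$
(Bonferroni). Note the clipping floor: with fewer than $m/\alpha$
replicates the test cannot reject and the package warns. Among converged
epochs the one of greatest estimated entropy is returned.

Optimization starts from a Gaussian fit of the flow (reverse-KL stochastic
gradients) whose mean and spread are model-specific: the support-box center
with 1/8-width spread by default; a wide spread (sd 4) for the linear
dynamical system, whose oscillation band lives at $|a_{12}|,|a_{21}|\approx
2\pi$; a point inside the noise-stable band for the V1 circuit (below); and, for
the superior-colliculus network, the net-inhibitory regime
($\lambda_{all}\approx -4$) where the bounded response stays mid-range and
task competition is possible — a model-informed initialization in the same
spirit as the search-informed conductance-model start of the original
study.

Two optimization regimes emerged while developing the package, and both are
exposed through the hyperparameters. With a large penalty ($c_0$ of the
order used for the conductance model) constraints are enforced quickly but
the multiplier update $\eta \leftarrow \eta + c\hat R$ can overshoot and
destabilize late epochs. With a small $c_0$ and more epochs the multipliers
converge smoothly and predictive means land much closer to their targets at
the cost of wall time; the low-dimensional benchmark runs below use this
regime. Entropy maximization is mode-seeking: once the flow abandons a
symmetric mode, no gradient signal recovers it, so gentle early penalties
and a wide initialization also protect multimodality (the two sign patterns
of the oscillating linear system).

# The circuit-model zoo

**2-D linear dynamical system** ($\tau = 1$ s). Statistics are the real and
imaginary parts of the primary eigenvalue of $A$, closed-form from the
characteristic polynomial (the discriminant uses $\mathrm{tr}(A/\tau)^2 -
4\det(A/\tau)$, the characteristic-polynomial-correct scaling, which at
$\tau = 1$ equals the printed formula); gradients are analytic. The
oscillation property constrains $\mathrm{real}(\lambda_1)$ to $0 \pm 0.25$
and $\mathrm{imag}(\lambda_1)$ to $2\pi \pm \pi/5$ (a 1 Hz band).

**Rank-2 RNN.** $W = UV^\top$ with $U = [U_1\,U_2] + g\chi_U$, entries of
$z$ in $[-1,1]^{4N}$. $\mathrm{real}(\lambda_1)$ comes from the
trace/determinant formula on $W_r = V^\top U$; $\lambda_1^s$ is the top
eigenvalue of the symmetrized connectivity with the standard
eigenvector-outer-product derivative. At $N = 2$ all statistics and
gradients are vectorized in closed form; the per-row reference path (any
$N$) validates them. Stable amplification requires
$\mathrm{real}(\lambda_1) < 1 < \lambda_1^s$; the property centers them at
$0.5$ and $1.5$ with sd $0.25$.

**STG subcircuit.** Five Morris–Lecar-style conductance neurons (15 state
dimensions: five voltages, five potassium gates, five
hyperpolarization-current gates), Euler–Maruyama at $dt = 25$ ms for 300
samples, with free electrical-coupling and hub-synapse conductances
$z = (g_{el}, g_{synA})$ in nS. Circuit wiring follows the source circuit
this model adopts: the fast pair and slow pair mutually inhibit at 5 nS;
the hub couples electrically to one cell of each pair and receives
$g_{synA}$ inhibition from the other two. The potassium rate constant
$\phi_N = 0.002\,\mathrm{ms}^{-1}$ is the Morris–Lecar value of that source
model. Initial voltages are a fixed, staggered state
$(-65,-40,-55,-65,-40)$ mV with gates at steady state: a deterministic
start keeps within-parameter frequency variability at the scale of the
injected current noise (pA), which the tight variance target
($0.025^2\,\mathrm{Hz}^2$) requires — with random initial states the
within-parameter variance alone exceeds the target, making the property
infeasible.

The differentiable frequency readout drops 20 burn-in samples, rectifies
about 0 mV, applies a 20-sample moving average, *centers the filtered
trace*, projects onto complex exponentials at 0.00–1.00 Hz (0.01 Hz grid),
and takes the soft-argmax ($\beta = 100$) frequency-index expectation.
Centering is a deliberate numerical choice: a rectified spike train has a
DC coefficient at least as large as every harmonic, so without it the bank
(which includes 0 Hz) would always report 0. Degenerate all-zero traces are
flagged and report 0 Hz.

**V1 stochastic stabilized supralinear network.** Four populations
(E, P, S, V) with $\phi(v) = \mathrm{relu}(v)^2$, printed connectivity and
inputs, $\tau = 1$ ms, OU input noise with $\tau_{\text{noise}} = 5$ ms and
$\tilde\sigma = \sigma\sqrt{1+\tau/\tau_{\text{noise}}}$ so that $\sigma$
parameterizes input variability without recurrence. Default contrast is 1
(full-contrast stimulus). The supralinear loop has a finite basin: noise
can push trajectories into runaway growth. Trials whose rates exceed
$10^5$ Hz are aborted and flagged (NaN from the blow-up step); parameter
draws whose trial-averaged statistic is non-finite are dropped from batch
averages with a logged count, and an epoch aborts if they exceed 10% of a
batch. The fluctuation gain is steep: the $s_E = 5$ Hz band lies at
$\sigma_E, \sigma_P \lesssim 0.05$, which is where EPI runs are
initialized. The Lyapunov oracle solves
$S\Lambda + \Lambda S^\top = 2\,\mathrm{diag}(\tilde\sigma^2)$ with
$S = I - W\phi'(v^*)$, the white-noise ($\tau_{\text{noise}} = \tau$)
limit of the linearized input fluctuations, and is checked against direct
simulation of that linearized system.

**Superior-colliculus network.** Four populations (LP, LA, RP, RA) with the
symmetric four-parameter connectivity, shifted-tanh response bounded in
$(0,1)$, $\tau = 90$ ms, $dt = 24$ ms over 1.8 s trials, and the printed
five-component input sequence. The Euler–Maruyama noise term uses
$\sigma = 0.2$ (the printed "variance 0.22" read as $0.2^2$), applied as
$\sigma\sqrt{dt}\,\xi/\tau$; internal variables start at $u(0) = 0$ and
inputs are evaluated at the left endpoint of each step. Soft decisions
$\mathrm{sigmoid}(100\,(x_{LP}-x_{RP}))$ at $t = 1.8$ s give Pro/Anti
accuracies on Left-stimulus trials (the circuit is mirror-symmetric).
Optogenetic silencing scales activity by $1-\gamma$ during
$0.8 < t < 1.2$ s. The connectivity eigenvalues are the printed linear map
$\lambda = 4A^\top z$; eigenmode perturbation directions are the normalized
columns of $A$, orthogonal and independent of $z$, with the printed column
order (all, side, task, diag).

Gradients for the three simulation-based models are pathwise central finite
differences with common random numbers: the same seed reproduces the same
noise for any $z$, so differencing along $z$ differentiates through the
reparameterized noise path. Step sizes are fixed per model (0.04/0.02 nS
for the STG conductances, 0.004 for the V1 noise scales, 0.02 for SC
weights), chosen at the scale where the statistic responds smoothly; the
soft-argmax frequency readout is effectively quantized at 0.01 Hz, so its
finite differences act as stochastic subgradients.

# Sensitivity toolbox

At any interior point the log-density Hessian (central differences of the
analytic gradient) is symmetrized and eigendecomposed with eigenvalues
ascending; the first eigenvector is the sensitivity dimension, and sign
degeneracy is fixed by a per-analysis convention (positive $g_{synA}$ for
the STG; negative $hW$ for the SC). Clamped modes are found by fixed-step
gradient ascent with the documented learning-rate schedule (500 steps at
$5\times10^{-3}$, then 200 at $10^{-3}$, halving every 100 steps), no line
search, with boundary projection; continuation warm-starts each anchor from
the previous mode, and the first from the closest of 500 flow samples.
Sample grouping is nearest-mode in full-coordinate Euclidean distance (ties
to the lowest index). Perturbation sweeps report simulated statistics,
standard errors and log density along $z^* + \delta v$, flagging
out-of-support points rather than dropping them.

# What the tests and benchmark runs show — and what they do not

The package's statistical benchmarks run at reduced scale so the whole
suite completes on one CPU: the maximum-entropy oracle (identity model with
unit moment constraints, whose solution is the standard normal) at batch
200; the linear-system run at batch 1000 with 400 iterations per epoch and
up to 22 epochs; the RNN run at batch 400 with 250 iterations and up to 8
epochs; and deliberately small conductance/V1/SC runs (batches 40/20/12,
150 iterations, 3 epochs, 1/10/10 inner trials). The full-scale
settings of the original applications (thousands of iterations per epoch,
hundreds of samples per batch, 100–200 inner trials) remain the package
defaults via `defaultHyperparams`. At the reduced scale the optimizer's
stochastic residual bias in predictive means is of the order of 1–3% —
comparable to, and sometimes larger than, the Monte-Carlo standard error of
a 1000-sample predictive mean, and the small conductance/V1/SC runs
demonstrate constraint-error reduction and the qualitative contracts rather
than full convergence. Passing tests therefore show the machinery is
correct and the method behaves as designed; they do not certify that every
reduced run reproduces full-scale convergence, and none of this bears on
real biological data, which the underlying models idealize heavily.

Known limitations: entropy estimation is Monte-Carlo (no control variates);
mode-seeking collapse of symmetric modes is mitigated, not eliminated;
the penalty-growth test stalls once constraint norms plateau, leaving
multiplier convergence to do the final work; and the quantized frequency
readout makes conductance-model gradients piecewise constant at fine
scales.
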