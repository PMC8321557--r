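#' @title Class definitions
#' @name epinfer-classes
#' @description S4 containers for flows, emergent properties, circuit models,
#'   optimizer results and sensitivity reports.
NULL

## ---------------------------------------------------------------- flow types

#' Architecture of a real NVP coupling stack
#'
#' Describes the deep probability distribution \eqn{g_\theta}: the number of
#' affine coupling stages, the size of the conditioner networks (fully
#' connected, tanh hidden layers), the permutation scheme applied between
#' stages, and the dimensionality of the variable.
#'
#' @slot nCouplingStages number of affine coupling stages (>= 1)
#' @slot conditionerDepth number of hidden layers in each conditioner network
#' @slot conditionerWidth units per hidden layer
#' @slot permutation one of \code{"glow"} (fixed random permutation drawn at
#'   build time) or \code{"fixed-swap"} (swap the two coordinate halves)
#' @slot dim dimensionality D of the parameter vector
#' @export
setClass("FlowArchitecture",
  representation(nCouplingStages = "integer", conditionerDepth = "integer",
                 conditionerWidth = "integer", permutation = "character",
                 dim = "integer"),
  prototype(nCouplingStages = 3L, conditionerDepth = 2L,
            conditionerWidth = 50L, permutation = "glow", dim = 2L))

setValidity("FlowArchitecture", function(object) {
  msg <- character()
  if (object@nCouplingStages < 1L) msg <- c(msg, "need >= 1 coupling stage")
  if (object@conditionerDepth < 1L) msg <- c(msg, "conditioner depth >= 1")
  if (object@conditionerWidth < 1L) msg <- c(msg, "conditioner width >= 1")
  if (!object@permutation %in% c("glow", "fixed-swap"))
    msg <- c(msg, "permutation must be 'glow' or 'fixed-swap'")
  if (object@dim < 1L) msg <- c(msg, "dim >= 1")
  if (length(msg)) msg else TRUE
})

#' Box support of a flow distribution
#'
#' Per-dimension bounds; either side may be infinite. The support map of the
#' flow (an elementwise scaled logistic for two-sided dimensions, softplus for
#' half-open ones, identity for unbounded ones) targets this box.
#'
#' @slot lower,upper numeric vectors of length D (model units); \code{-Inf} /
#'   \code{Inf} mark open ends
#' @export
setClass("BoxSupport",
  representation(lower = "numeric", upper = "numeric"))

setValidity("BoxSupport", function(object) {
  if (length(object@lower) != length(object@upper))
    return("lower/upper length mismatch")
  bad <- is.finite(object@lower) & is.finite(object@upper) &
    object@lower >= object@upper
  if (any(bad)) return("degenerate box: lower >= upper")
  TRUE
})

#' A bounded-support deep probability distribution
#'
#' Real NVP coupling stack over a standard-normal base variable, composed with
#' a support map onto a box. Weights are stored flat; \code{layout} records
#' how they unpack into per-stage conditioner networks and which permutations
#' and coupling masks each stage uses.
#'
#' @slot architecture a \linkS4class{FlowArchitecture}
#' @slot support a \linkS4class{BoxSupport}
#' @slot weights flat numeric parameter vector theta
#' @slot layout internal weight/mask layout (list; built by \code{buildFlow})
#' @export
setClass("FlowDistribution",
  representation(architecture = "FlowArchitecture", support = "BoxSupport",
                 weights = "numeric", layout = "list"))

setValidity("FlowDistribution", function(object) {
  D <- object@architecture@dim
  if (length(object@support@lower) != D)
    return("support dimension does not match architecture dim")
  if (!is.null(object@layout$nParams) &&
      length(object@weights) != object@layout$nParams)
    return("weight vector length does not match layout")
  TRUE
})

## ----------------------------------------------------- emergent property

#' An emergent property: statistics with target means and variances
#'
#' Defines the computation of interest as first- and second-moment constraints
#' on a vector of statistics f(x; z) of simulated circuit activity. The
#' statistic itself is supplied by the circuit model via
#' \code{\link{circuitStatistics}}; this object holds the targets.
#'
#' @slot statNames labels of the m_f statistics
#' @slot mu target means (statistic units)
#' @slot sigma2 target variances (squared units), all > 0
#' @slot innerTrials number of independent simulations averaged per parameter
#'   draw when evaluating the statistics
#' @export
setClass("EmergentProperty",
  representation(statNames = "character", mu = "numeric", sigma2 = "numeric",
                 innerTrials = "integer"))

setValidity("EmergentProperty", function(object) {
  msg <- character()
  mf <- length(object@mu)
  if (mf < 1L) msg <- c(msg, "need at least one statistic")
  if (length(object@sigma2) != mf) msg <- c(msg, "mu/sigma2 length mismatch")
  if (any(object@sigma2 <= 0)) msg <- c(msg, "all variances must be > 0")
  if (length(object@statNames) != mf) msg <- c(msg, "statNames length mismatch")
  if (object@innerTrials < 1L) msg <- c(msg, "innerTrials >= 1")
  if (length(msg)) msg else TRUE
})

#' Sufficient statistics of the maximum-entropy problem
#'
#' The constraint vector of the exponential-family view: T(z) stacks the
#' per-parameter averaged statistics and their squared deviations from the
#' fixed target means, and \code{muOpt = c(mu, sigma2)} stacks the constraint
#' values. \code{m = 2 * m_f} always.
#'
#' @slot property the defining \linkS4class{EmergentProperty}
#' @slot muOpt constraint values, means then variances
#' @export
setClass("SufficientStatistics",
  representation(property = "EmergentProperty", muOpt = "numeric"))

setValidity("SufficientStatistics", function(object) {
  if (length(object@muOpt) != 2L * length(object@property@mu))
    return("muOpt must have length 2 * m_f")
  if (!isTRUE(all.equal(object@muOpt,
                        c(object@property@mu, object@property@sigma2))))
    return("muOpt must equal c(mu, sigma2)")
  TRUE
})

## ------------------------------------------------------------- circuit models

#' Virtual parent of all circuit models
#'
#' A circuit model couples a differentiable simulator to emergent-property
#' statistics. Concrete subclasses implement \code{\link{simulateCircuit}},
#' \code{\link{circuitStatistics}}, \code{\link{paramNames}} and
#' \code{\link{supportBox}}.
#' @export
setClass("CircuitModel", representation("VIRTUAL", name = "character"))

#' Two-dimensional linear dynamical system
#'
#' \eqn{\tau \dot x = A x} with free parameters z = (a11, a12, a21, a22).
#' Statistics: real and imaginary part of the primary eigenvalue of A,
#' computed in closed form from the characteristic polynomial.
#'
#' @slot tau time constant in seconds (1 s)
#' @export
setClass("LDS2D", contains = "CircuitModel",
  representation(tau = "numeric"),
  prototype(name = "lds2d", tau = 1))

#' Rank-2 recurrent network connectivity model
#'
#' Connectivity W = U V' with U = [U1 U2] + g*chi_U, V = [V1 V2] + g*chi_V,
#' chi entries iid standard normal, and z = (U1, U2, V1, V2) in [-1,1]^(4N).
#' Statistics: real(lambda1) of W via the rank-reduced 2x2 matrix Wr = V'U,
#' and the maximum eigenvalue lambda1s of (W + W')/2.
#'
#' @slot N number of neurons
#' @slot g random connectivity strength
#' @export
setClass("Rank2RNN", contains = "CircuitModel",
  representation(N = "integer", g = "numeric"),
  prototype(name = "rnn", N = 2L, g = 0.01))

#' Stomatogastric-ganglion five-neuron conductance subcircuit
#'
#' Conductance-based model of two fast cells, two slow cells and a hub neuron,
#' with free parameters z = (g_el, g_synA) in nS. The 15-dimensional state
#' holds five membrane potentials plus per-neuron potassium (N) and
#' hyperpolarization (H) gates. The emergent-property statistic is the hub
#' neuron spiking frequency via a differentiable soft-argmax readout.
#'
#' @slot dt integration step (ms)
#' @slot nSteps simulated samples per trace
#' @slot noiseSd current noise standard deviation (nA)
#' @export
setClass("STGCircuit", contains = "CircuitModel",
  representation(dt = "numeric", nSteps = "integer", noiseSd = "numeric"),
  prototype(name = "stg", dt = 25, nSteps = 300L, noiseSd = 1e-3))

#' V1 stochastic stabilized supralinear network (four populations)
#'
#' Rate model of E, P (parvalbumin), S (somatostatin) and V (VIP) populations
#' with supralinear transfer phi(v) = relu(v)^2 and slow Ornstein-Uhlenbeck
#' input noise. Free parameters z = (sigma_E, sigma_P, sigma_S, sigma_V) set
#' the noise scale per population; the statistic is the standard deviation
#' s_E of the E rate about its stimulus-evoked steady state.
#'
#' @slot W fixed 4x4 effective connectivity
#' @slot hb,hc baseline and contrast input vectors
#' @slot contrast stimulus contrast in [0, 1]
#' @slot tau,tauNoise rate and noise time constants (ms)
#' @slot dt step (ms); @slot nSteps samples per trace
#' @export
setClass("V1SSN", contains = "CircuitModel",
  representation(W = "matrix", hb = "numeric", hc = "numeric",
                 contrast = "numeric", tau = "numeric", tauNoise = "numeric",
                 dt = "numeric", nSteps = "integer"))

#' Superior-colliculus task-switching network
#'
#' Four functionally defined populations (left/right Pro and Anti) with
#' symmetric connectivity parameterized by z = (sW, vW, hW, dW), performing
#' the Pro (orient-toward) and Anti (orient-away) tasks on interleaved cued
#' trials. Statistics: soft decision accuracies in each task.
#'
#' @slot tau time constant (s); @slot dt step (s); @slot trialLength trial
#'   duration (s); @slot noiseSd Euler-Maruyama noise scale
#' @slot inputs named amplitudes of the five trial input components
#' @slot betaTheta sharpness of the sigmoid Heaviside approximation
#' @export
setClass("SCNetwork", contains = "CircuitModel",
  representation(tau = "numeric", dt = "numeric", trialLength = "numeric",
                 noiseSd = "numeric", inputs = "numeric",
                 betaTheta = "numeric"))

#' Identity "circuit": statistics are the parameters themselves
#'
#' Diagnostic model whose simulation is x = z and whose statistics are the
#' coordinates of z. With first/second moment constraints the maximum-entropy
#' solution is Gaussian, giving an exact oracle for the optimizer.
#'
#' @slot dim dimensionality
#' @export
setClass("IdentityModel", contains = "CircuitModel",
  representation(dim = "integer"),
  prototype(name = "identity", dim = 2L))

## -------------------------------------------------------------- optimizer

#' Hyperparameters of the augmented-Lagrangian optimization
#'
#' @slot c0 initial penalty coefficient
#' @slot beta penalty growth factor (> 1; 2 or 4 in practice)
#' @slot gamma required constraint-norm reduction ratio per epoch (0.25)
#' @slot imax Adam iterations per epoch
#' @slot kmax maximum number of epochs
#' @slot batchN samples per stochastic-gradient iteration (even)
#' @slot lr Adam learning rate
#' @slot Ntest batch size of the convergence hypothesis test
#' @slot testReps number of constraint-mean replicates in the test
#' @export
setClass("ALHyperparams",
  representation(c0 = "numeric", beta = "numeric", gamma = "numeric",
                 imax = "integer", kmax = "integer", batchN = "integer",
                 lr = "numeric", Ntest = "integer", testReps = "integer"),
  prototype(c0 = 10, beta = 2, gamma = 0.25, imax = 1000L, kmax = 10L,
            batchN = 200L, lr = 1e-3, Ntest = 100L, testReps = 200L))

setValidity("ALHyperparams", function(object) {
  msg <- character()
  if (object@c0 <= 0) msg <- c(msg, "c0 > 0")
  if (object@beta <= 1) msg <- c(msg, "beta > 1")
  if (object@gamma <= 0 || object@gamma >= 1) msg <- c(msg, "0 < gamma < 1")
  if (object@batchN %% 2L != 0L) msg <- c(msg, "batchN must be even")
  if (object@Ntest < 2L) msg <- c(msg, "Ntest >= 2")
  if (length(msg)) msg else TRUE
})

#' Result of an EPI fit
#'
#' @slot bestFlow flow of the selected epoch (converged epoch of greatest
#'   entropy when any epoch converged, else the final epoch)
#' @slot bestEpoch selected epoch index
#' @slot converged TRUE when some epoch passed the convergence test
#' @slot history per-epoch records: entropy, ||R||, p-values, eta, c
#' @slot eta final Lagrange multipliers
#' @slot penalty final penalty coefficient
#' @slot seed integer seed of the run
#' @slot config configuration snapshot (list)
#' @export
setClass("EPIResult",
  representation(bestFlow = "FlowDistribution", bestEpoch = "integer",
                 converged = "logical", history = "data.frame",
                 eta = "numeric", penalty = "numeric", seed = "integer",
                 config = "list"))

## ------------------------------------------------------------- sensitivity

#' Hessian sensitivity report at a parameter point
#'
#' @slot location parameter point z
#' @slot hessian D x D symmetric Hessian of log q at z (1/units^2)
#' @slot eigenvalues ascending (most negative, i.e. most sensitive, first)
#' @slot eigenvectors columns matched to eigenvalues, unit norm, sign fixed by
#'   the convention
#' @slot signConvention list(index, sign) fixing eigenvector sign degeneracy
#' @export
setClass("SensitivityReport",
  representation(location = "numeric", hessian = "matrix",
                 eigenvalues = "numeric", eigenvectors = "matrix",
                 signConvention = "list"))

setValidity("SensitivityReport", function(object) {
  H <- object@hessian
  if (max(abs(H - t(H))) > 1e-6) return("hessian not symmetric to 1e-6")
  nrm <- sqrt(colSums(object@eigenvectors^2))
  if (any(abs(nrm - 1) > 1e-6)) return("eigenvectors must be unit norm")
  if (is.unsorted(object@eigenvalues)) return("eigenvalues must ascend")
  TRUE
})

#' A chain of clamped-coordinate modes of a flow
#'
#' @slot fixedIndex which coordinate was clamped
#' @slot anchors clamp values, in the order the chain was run
#' @slot modes matrix of mode points, one row per anchor
#' @slot logDensity log q at each mode
#' @export
setClass("ModeSet",
  representation(fixedIndex = "integer", anchors = "numeric",
                 modes = "matrix", logDensity = "numeric"))

setValidity("ModeSet", function(object) {
  if (nrow(object@modes) != length(object@anchors))
    return("one mode row per anchor required")
  if (length(object@anchors) &&
      any(object@modes[, object@fixedIndex] != object@anchors))
    return("clamped coordinate must equal its anchor exactly")
  TRUE
})
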