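#' Number of free parameters of a circuit model
#' @param model a \linkS4class{CircuitModel}
#' @return integer dimensionality of z
#' @export
setGeneric("paramDim", function(model) standardGeneric("paramDim"))

#' Labels of the free parameters of a circuit model
#' @param model a \linkS4class{CircuitModel}
#' @return character vector of length \code{paramDim(model)}
#' @export
setGeneric("paramNames", function(model) standardGeneric("paramNames"))

#' Parameter support box of a circuit model
#' @param model a \linkS4class{CircuitModel}
#' @return a \linkS4class{BoxSupport}
#' @export
setGeneric("supportBox", function(model) standardGeneric("supportBox"))

#' Simulate a circuit model at one parameter value
#'
#' @param model a \linkS4class{CircuitModel}
#' @param z numeric parameter vector of length \code{paramDim(model)}
#' @param seed integer seed for the simulation noise
#' @param ... model-specific options (e.g. \code{task}, \code{side},
#'   \code{gamma} for the SC model; \code{nTrials} for trial-based models)
#' @return a model-specific trajectory object (matrix or array of activity)
#' @export
setGeneric("simulateCircuit",
           function(model, z, seed, ...) standardGeneric("simulateCircuit"))

#' Emergent-property statistics (and their parameter gradients) for a batch
#'
#' Evaluates f(x; z) averaged over \code{nTrials} independent simulations per
#' parameter draw. When \code{withGrad} is TRUE, also returns the pathwise
#' gradient of the trial-averaged statistics with respect to z (closed form
#' for the LDS and RNN models; central finite differences with common random
#' numbers for the simulation-based models).
#'
#' @param model a \linkS4class{CircuitModel}
#' @param z n x D matrix of parameter draws (rows)
#' @param nTrials simulations averaged per draw
#' @param seed integer seed
#' @param withGrad also compute gradients?
#' @return list with \code{f} (n x m_f matrix) and \code{grad}
#'   (n x m_f x D array, or NULL)
#' @export
setGeneric("circuitStatistics",
           function(model, z, nTrials = 1L, seed = 1L, withGrad = FALSE)
             standardGeneric("circuitStatistics"))

#' Per-model default augmented-Lagrangian hyperparameters
#' @param model a \linkS4class{CircuitModel}
#' @return an \linkS4class{ALHyperparams}
#' @export
setGeneric("defaultHyperparams",
           function(model) standardGeneric("defaultHyperparams"))

#' Default flow architecture used for a circuit model
#' @param model a \linkS4class{CircuitModel}
#' @return a \linkS4class{FlowArchitecture}
#' @export
setGeneric("defaultArchitecture",
           function(model) standardGeneric("defaultArchitecture"))

#' Default Gaussian initialization of the flow for a circuit model
#'
#' Mean and standard deviation of the isotropic Gaussian the flow is fitted
#' to before the augmented-Lagrangian optimization. The default for bounded
#' models is the support-box center with 1/8-width spread; models whose
#' dynamics are unstable over part of the support (the V1 circuit) center
#' the initialization inside the stable region instead.
#'
#' @param model a \linkS4class{CircuitModel}
#' @return list with \code{mu} and \code{sd} vectors
#' @export
setGeneric("defaultInit", function(model) standardGeneric("defaultInit"))
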