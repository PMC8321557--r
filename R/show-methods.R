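## show() methods for the user-facing S4 classes.

setMethod("show", "FlowArchitecture", function(object) {
  cat(sprintf(
    "FlowArchitecture: %d coupling stages, %d x %d conditioners, %s permutations, D = %d\n",
    object@nCouplingStages, object@conditionerDepth, object@conditionerWidth,
    object@permutation, object@dim))
})

setMethod("show", "BoxSupport", function(object) {
  cat("BoxSupport:", paste(sprintf("[%g, %g]", object@lower, object@upper),
                           collapse = " x "), "\n")
})

setMethod("show", "FlowDistribution", function(object) {
  cat("FlowDistribution over D =", object@architecture@dim,
      "with", length(object@weights), "weights\n")
  show(object@architecture)
  show(object@support)
})

setMethod("show", "EmergentProperty", function(object) {
  cat("EmergentProperty (", length(object@mu), "statistic(s),",
      object@innerTrials, "inner trial(s) ):\n")
  for (i in seq_along(object@mu))
    cat(sprintf("  %s: mean %g, variance %g\n", object@statNames[i],
                object@mu[i], object@sigma2[i]))
})

setMethod("show", "EPIResult", function(object) {
  cat("EPIResult:", if (object@converged) "converged" else "NOT converged",
      "| best epoch", object@bestEpoch, "of", nrow(object@history), "\n")
  cat(sprintf("  entropy %.3f nats, ||R|| = %.4g, min p = %.3g, c = %.3g\n",
              object@history$entropy[object@bestEpoch],
              object@history$normR[object@bestEpoch],
              object@history$minP[object@bestEpoch], object@penalty))
})

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport at z = (",
      paste(signif(object@location, 4), collapse = ", "), ")\n")
  cat("  eigenvalues (ascending):",
      paste(signif(object@eigenvalues, 4), collapse = ", "), "\n")
  cat("  sensitivity dimension v1:",
      paste(signif(object@eigenvectors[, 1], 4), collapse = ", "), "\n")
})

setMethod("show", "ModeSet", function(object) {
  cat("ModeSet:", length(object@anchors), "mode(s), coordinate",
      object@fixedIndex, "clamped\n")
})
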