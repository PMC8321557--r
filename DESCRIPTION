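Package: epinfer
Title: Emergent Property Inference for Mechanistic Neural-Circuit Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains bounded-support normalizing-flow distributions (real NVP
    affine coupling stacks) over the parameters of mechanistic neural-circuit
    models so that the models' emergent-property statistics match prescribed
    means and variances at maximum entropy, using augmented-Lagrangian
    constrained stochastic optimization. Ships a zoo of differentiable circuit
    models (2-D linear dynamical system, rank-2 recurrent network,
    stomatogastric-ganglion conductance subcircuit, V1 stochastic stabilized
    supralinear network, superior-colliculus task-switching network) and tools
    to interrogate a learned distribution: log-density Hessian sensitivity
    dimensions, constrained mode finding, mode-based sample grouping, and
    perturbation sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
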