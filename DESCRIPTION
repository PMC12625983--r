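Package: driftlab
Title: Representational Drift as Diffusion in Neural-Network Weight Solution Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates representational drift as random diffusion restricted to
    the synaptic-weight solution space of a single-hidden-layer
    clipped-threshold-linear network with a fixed linear readout. Provides the
    eta-coordinate system that separates input-current-relevant weight
    combinations from unconstrained ones, a constrained drift step with
    threshold-event handling and a per-neuron weight-norm bound, memory
    allocation, gradient-descent learning in weight and eta coordinates, and
    experiment protocols quantifying robustness to weight perturbations,
    learnability, and continual-learning interference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
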