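Package: agentsim
Title: Agent-Based Simulation Engine for Cellular, Tumor and Epidemic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular agent-based simulation engine for desk-scale
    biological models: agents with attachable behaviors, operations with
    per-operation execution frequencies, deferred agent creation and
    removal, a uniform-grid spatial index for fixed-radius neighborhood
    queries, extracellular scalar fields (static Gaussian guidance cues
    and an explicit finite-difference diffusion grid), and overdamped
    pairwise mechanics between spherical agents. Ships three validated
    demonstration models: a spatial SIR epidemic on a toroidal domain
    compared against the Kermack-McKendrick ODE system and calibrated by
    particle swarm optimization, a tumor spheroid with growth, division,
    Brownian migration and apoptosis whose diameter is derived from the
    convex hull of the cell cloud, and gradient-guided pyramidal-cell
    dendritic growth with tapering, stochastic branching, morphometrics
    and SWC import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
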