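Package: coupledGTPase
Title: Multi-Timescale Modeling of a Golgi-Localized Coupled GTPase Circuit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of a coupled monomeric
    (Arf1-family) and trimeric (Gi-family) GTPase switch circuit on the Golgi,
    built from normalized-Hill logic-based ordinary differential equations, with
    a downstream secrete-and-sense module coupling secretion to cell number.
    Includes Ornstein-Uhlenbeck noise channels injected into the stimulus,
    species or connections with ensemble statistics; steady-state dose-response
    sweeps with Hill and linear curve fitting for dose-response-alignment
    (DoRA) and ultrasensitivity quantification; time-course parameter fitting
    against fold-change datasets using normalized RMSE acceptance thresholds;
    local logarithmic sensitivity analysis; and differential shortest-path
    perturbation analysis of seeded protein-protein interaction networks.
    Synthetic-data generators supply time-course datasets and PPI fixtures with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    igraph,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lhs,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
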