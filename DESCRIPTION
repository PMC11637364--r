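Package: jrfic
Title: Jansen-Rit Brain Network Simulation with Dynamic Feedback
    Inhibition Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of delay-coupled Jansen-Rit neural
    mass networks with a homeodynamic inhibitory plasticity mechanism
    (dynamic feedback inhibition control, dFIC) that tunes per-region
    inhibitory coupling until the long-term average pyramidal activity
    reaches a chosen target level.  Includes deterministic and
    stochastic Heun integration with conduction delays, brute-force
    attractor atlases of the isolated node over external input and
    inhibitory scaling, dFIC equilibrium and target-feasibility
    analysis, Balloon-model BOLD synthesis, and a fitting stack with
    functional connectivity, sliding-window FC dynamics,
    Kolmogorov-Smirnov similarity, a multimodal fitness score, Welch
    spectra, and Poincare-map regime classification.  Synthetic
    connectome and surrogate empirical-data generators allow the whole
    pipeline to run without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
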