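Package: tdperception
Title: Hierarchical Bayesian Temporal Discounting, Time Perception, and
    Episodic Future Thinking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference pipeline for behavioral studies of
    temporal discounting in clinical and control groups. Generates synthetic
    cohorts with questionnaire covariates and latent behavioral parameters,
    simulates adaptive-staircase and fixed-item intertemporal choice tasks as
    well as circle-size time-perception rating sessions, fits a hierarchical
    Bayesian hyperbolic discounting model (softmax choice rule) with separate
    group-level distributions via Gibbs sampling, performs per-participant
    Bayesian model selection among linear, quadratic, and power rating laws
    using the deviance information criterion, applies the circle-size
    correction that inverts the participant-specific circle-production power
    law, and reproduces the group-level statistical layer (Welch tests,
    correlation comparisons, Cronbach's alpha, multiple regression on
    log discount rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
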