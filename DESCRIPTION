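Package: rpsim
Title: Replicase-Parasite RNA-World Dynamics at Two Observation Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the eco-evolutionary stability of a minimal
    RNA-world replicator network consisting of RNA replicases and the
    parasitic templates they inadvertently copy.  The package provides the
    closed-form well-mixed analysis of the system (steady state, persistence
    inequality, linearized growth rate, and a pendulum-equation reduction of
    the homogeneous dynamics), a discretized 2D reaction-diffusion simulator
    with an evolving parasite-affinity field, a microscopic Brownian-dynamics
    multi-agent simulator of the same chemistry, and shared metrics for
    outcome classification, oscillation statistics, and the traveling-wave
    persistence condition.  The two simulators are parameterized comparably
    so that macroscopic (density-field) and microscopic (single-molecule)
    descriptions can be cross-validated.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
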