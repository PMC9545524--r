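Package: motortug
Title: Stochastic Tug-of-War Simulation and Trace Analysis for
    Kinesin-Dynein Motor Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven (Gillespie) stochastic stepping simulation of a
    single kinesin motor mechanically coupled to an activated
    dynein-dynactin-BicD2 (DDB) complex through elastic linkages, with
    load-dependent stepping (linear force-velocity), Bell-model
    detachment, and first-order reattachment. Includes the companion
    single-molecule trace-analysis pipeline used for kymograph-derived
    position-time traces: camera-frame averaging, trace and instantaneous
    velocities, piecewise-constant-velocity segmentation with pause and
    directional-switch calling, duration-weighted velocity distributions,
    and bootstrap single-exponential dwell-time fits. A synthetic-trace
    generator with full ground truth emulates the statistical structure
    of TIRF tracking data so the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
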