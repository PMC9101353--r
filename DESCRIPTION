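Package: sfmech
Title: Mechanics of Peripheral Stress Fibers Under Stretch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the mechanical response of peripheral actin
    stress fibers in micropatterned cells subjected to substrate stretch.
    Implements an active viscoelastic bundle model (two springs, a dashpot and
    a Gaussian myosin motor element in a three-element arrangement), its
    closed-form short- and long-time limits, a strain-gated elasticity law with
    fresh-actin recruitment kinetics, and the dimensionless local
    cortical-tension dynamics of a bundle segment. Provides measurement
    operators for fluorescence data (circular-arc curvature fitting, intensity
    kymograph construction, photobleaching correction, relative normalisation,
    segment averaging, focal-adhesion and mid-fiber landmark detection),
    least-squares estimation of all mechanical parameters (strain-response
    slopes, relaxation time scales, recruitment index, local ODE groups), and
    a synthetic-data generator that emulates the microscopy observables so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
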