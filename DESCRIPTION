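Package: lfpdyn
Title: Rotational Low-Frequency Dynamics of Motor-Cortical Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for low-frequency (delta-band) dynamics of
    multichannel motor-cortical local field potentials (LFPs) and their
    relationship to movement kinematics. Implements zero-phase band
    filtering, within-area mean referencing and PCA with a rotational
    orientation convention; submovement and K-complex event detection with
    interval rhythmicity statistics; areal-velocity geometry of LFP
    principal-component trajectories; a Fourier-parameterized areal-velocity
    decoder of submovement speed and direction with leave-one-out
    cross-validation and shuffle significance; a trace-zero 2x2 linear
    dynamical model of planar LFP trajectories with cross-condition
    generalization and a white-noise null calibration; circular statistics
    for event- and spike-locked phase analyses; and a synthetic session
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
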