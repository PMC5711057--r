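Package: mlcport
Title: Monte Carlo Multileaf Collimator Transport and VMAT Plan QA
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo toolchain for photon transport through a
    Varian-style multileaf collimator (MLC) and the downstream quality-assurance
    computations used in volumetric-modulated arc therapy (VMAT) plan
    verification. The MLC model is a simplified particle transport through a
    fully parameterized two-bank leaf geometry (intraleaf thickness variation,
    tongue-and-groove steps, interleaf gaps, rounded leaf tips) in which only
    primary photon attenuation and single Compton scatter are carried. A
    meterset-synchronized dynamic source replays control-point sequences for
    dynamic-MLC and VMAT deliveries. QA tools include absolute-dose conversion
    by linear calibration, a locally adaptive Savitzky-Golay denoising filter
    driven by a chi-squared fit test, 3D gamma-index dose comparison,
    transmission analysis, and tungsten density calibration against a target
    transmission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
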