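Package: angioflow
Title: Sparse-Acquisition Frame Synthesis for Digital Subtraction Angiography
Version: 0.1.0
Authors@R:
    person("angioflow", "developers", email = "angioflow@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for radiation dose reduction in digital
    subtraction angiography (DSA) by temporal frame synthesis.  Provides a
    procedural angiography simulator (vessel trees, gamma-variate contrast
    bolus dynamics, 2D fixed-view and 3D rotational acquisition, guidewires,
    subtraction artifacts) with exact ground truth; a compact flow-guided
    frame-interpolation network (direction-aware convolutions, bidirectional
    optical flow with backward warping, spatio-temporal attention) trained
    with a composite pixel/structural/perceptual loss under a cosine-annealed
    AdamW schedule; the 1-in-(N+1) sparse acquisition and reconstruction
    pipeline with dose accounting; image-quality evaluation (SSIM, PSNR, MSE,
    bootstrap confidence intervals, time-intensity-curve error, guidewire tip
    localization); and reader-study statistics (visual Turing test confusion
    matrices, Fleiss' kappa, weighted Cohen's kappa, exact Wilcoxon
    signed-rank, and standard group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
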