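Package: spadkit
Title: Physics-Informed Simulation, Calibration and Enhancement of SPAD Single-Photon Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-photon avalanche diode (SPAD) array imaging.
    Provides a multi-source physical noise simulator for 1-bit photon-counting
    frames (shot noise with per-pixel photon detection efficiency, Poisson dark
    counts, one-frame-memory afterpulsing and neighbour crosstalk), a dark-frame
    calibration procedure that recovers per-pixel noise parameter maps by event
    classification, a synthesizer for paired low-bit low-resolution measurement /
    high-resolution ground-truth datasets built on procedural phantoms or user
    images, a compact gated-fusion window-attention transformer for joint
    denoising and super-resolution trained with a hybrid L1/perceptual/SSIM
    loss (including a small tape-based reverse-mode differentiation engine),
    PSNR/SSIM evaluation utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
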