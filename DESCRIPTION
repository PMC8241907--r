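Package: octplaque
Title: Coronary Plaque Characterization from Intravascular OCT with a
    Two-Pathway Cascade Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes atherosclerotic plaque composition (fibrous,
    calcified, lipid) in polar-coordinate intravascular optical coherence
    tomography pullbacks. Provides dynamic-programming lumen-boundary and
    guidewire-shadow detection, a region-of-interest band construction,
    patch extraction with flip augmentation and exact class balancing, a
    two-pathway patch convolutional network (local and global receptive
    fields) with a cascaded second stage conditioned on first-stage class
    probability maps, convolutionalized dense whole-image inference,
    two-phase training for class-prior calibration, and per-class
    segmentation evaluation statistics. Includes a synthetic polar OCT
    phantom generator with analytic ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
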