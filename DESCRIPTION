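Package: hsiderm
Title: Hyperspectral Photometric-Stereo Pipeline for Skin Lesion Classification
Version: 0.1.0
Authors@R:
    person("hsiderm", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Re-implementation of a hand-held hyperspectral skin-imaging
    analysis pipeline: Lambertian photometric-stereo reconstruction of
    per-waveband albedo and skin-surface models from multi-angle 33-band
    captures (477-891 nm), machine-learning pre-processing (annotation-driven
    masks, channel selection, window sampling, oversampling, flip
    augmentation), a dual-branch 3D/2D convolutional neural network for
    pigmented (melanoma / nevus / healthy) and non-pigmented (BCC / SCC /
    intradermal nevus / healthy) lesion classification, and lesion-level
    majority voting. Includes a synthetic capture generator with known ground
    truth so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
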