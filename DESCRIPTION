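Package: thermoprick
Title: Automated Reading of Skin Prick Tests from Paired Visible and
    Thermal Forearm Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated reading of skin prick allergy tests from
    pixel-correlated visible-spectrum and thermal (long-wave infrared)
    images of the forearm taken before and 15 minutes after allergen
    application.  The package locates the highlighter-marked allergen
    application sites with a U-Net segmentation model, completes partially
    detected 2x4 marker grids with a pitch-vector heuristic, aligns the
    pre-application thermal image to the post-application one (homography
    or rigid line-based registration) to form a 'delta' thermal image,
    and classifies each application site as reactive or non-reactive with
    a convolutional neural network fused with patient interview
    attributes.  A synthetic forearm-image generator with full ground
    truth (marker positions, inter-series transform, per-site labels)
    provides an end-to-end test bed; the neural-network engine
    (convolution, pooling, batch normalisation, Adam/AdamW) is
    implemented in compiled code within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
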