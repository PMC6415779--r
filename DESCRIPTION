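Package: ringalign
Title: Deformed Alignment and Averaging of Localization Microscopy Ring
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Template-free alignment and averaging of single-molecule
    localization microscopy (SMLM/STORM) images of semi-flexible
    ring-shaped structures such as ciliary distal appendages.  Individual
    structures are robustly fitted to ellipses and circularized to a
    common radius, then registered by exhaustive in-plane rotation search
    combined with subpixel translation estimation from upsampled discrete
    Fourier transform cross-correlation.  A tilt search about the x axis
    extends the registration to flat structures oriented randomly in 3D,
    and per-structure transforms can be transferred across color
    channels.  Includes a synthetic structure simulator with configurable
    symmetry, labeling efficiency and localization precision, plus
    Fourier ring correlation and rotational autocorrelation metrics for
    evaluating alignment quality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
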