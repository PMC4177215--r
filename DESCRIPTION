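Package: voxelenc
Title: Voxel-Based Encoding Models and Activity-Pattern Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voxel-based encoding models of visual fMRI responses.
    Builds a Gabor wavelet pyramid and log-magnitude image features, fits
    per-voxel linear encoding models by bootstrap-averaged gradient descent
    with early stopping, supports region-to-region (analogical) encoding
    models that use another region's voxel patterns as input channels,
    averages predictions from multiple models, and scores predicted against
    observed multi-voxel activity patterns with correlation-matrix
    identification, overall and per region of interest. Includes a synthetic
    data generator that simulates stimulus-driven voxel responses with
    controlled signal-to-noise ratio for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
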