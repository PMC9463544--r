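Package: ewdrs
Title: Extended-Wavelength Diffuse Reflectance Spectroscopy Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A model-based characterization platform for fiber-optic
    extended-wavelength diffuse reflectance spectroscopy (EWDRS, 500-1500 nm).
    Provides a Monte Carlo photon-transport engine for layered and voxelized
    tissue models measured with a seven-fiber contact probe, dual-band
    (VIS/NIR + SWIR) spectral preprocessing with matching-factor band merging,
    simulation-versus-measurement agreement analysis against 95% confidence
    bands, diagnostic peak-ratio characterization, sparse multinomial logistic
    regression classification with leave-one-out cross-validation, and a
    synthetic phantom/tissue data generator for end-to-end exercises.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
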