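Package: chondrosim
Title: Image-Based Electro-Quasistatic Modelling of Cartilage-Like Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automated pipeline from 3D cell-stack images to numerically
    estimated impedance and dielectric spectra of cartilage-like tissue.
    Provides a seeded synthetic generator for confocal-style image stacks of
    ellipsoidal chondrocytes with exact ground-truth labels; a classical 3D
    instance-segmentation chain (isotropic resampling, background flattening,
    auto-thresholding, physical-unit artifact filters, distance-transform
    watershed, moment-based ellipsoid fitting); instance-matching evaluation
    metrics (IoU-thresholded accuracy, precision, recall, F1); geometry
    assembly with intersection graphs, void repair, iso-surface extraction,
    Taubin smoothing and quadric edge-collapse decimation; an
    electro-quasistatic voxel admittance-network solver with a thin-layer
    membrane approximation, impedance spectra, transmembrane potentials and
    effective dielectric extraction; an analytic single-shell suspension
    model; and polynomial-chaos uncertainty quantification with first-order
    Sobol indices and surrogate-sampled prediction intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
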