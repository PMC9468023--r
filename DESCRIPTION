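Package: demtex
Title: Texture Analysis of Droplet Evaporation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-stage texture analysis for dark-field micrographs of dried
    droplet deposits (droplet evaporation method, DEM): automatic selection of
    full-texture 128x128 patches by overlap-limited random sampling,
    row/column skewness screening and PCA outlier removal; clustering of
    patches by texture similarity with a convolutional classifier, redefining
    clusters from confusion-matrix columns and propagating labels by iterative
    aggregation; and verification of cluster fractality through local
    connected fractal dimension (LCFD) histograms, a gray-level co-occurrence
    matrix (GLCM) baseline clustering, and two-sample Kolmogorov-Smirnov
    separability tests.  Ships a seeded generator of synthetic droplet-like
    textures (diffusion-limited aggregates, scattered particles, dilated
    skeletons) with smooth backgrounds and glare for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    EBImage,
    Rcpp,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
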