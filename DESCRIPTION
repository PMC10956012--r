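Package: polarmap
Title: Tissue Microstructural Composition Analysis for Mueller Matrix Microscopy
Version: 0.1.0
Authors@R:
    person("polarmap", "developers", email = "polarmap@example.org", role = c("aut", "cre"))
Description: Unsupervised mapping of tissue microstructure from Mueller matrix
    microscope images. Provides physical (Cloude coherency eigenvalue) filtering
    and Gaussian smoothing of 4x4 Mueller matrix images, per-pixel polarization
    basis parameters (Lu-Chipman polar decomposition, Mueller matrix
    transformation parameters, rotation-invariant element combinations),
    compression of pixels into polarization super-pixels by minibatch k-means,
    a Canberra-metric UMAP atlas with density trimming, single-linkage
    clustering and label spreading, cluster-area-proportion markers with group
    statistics (Welch t-tests, rank-sum AUC), and a synthetic Mueller phantom
    generator with known per-pixel class structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    FNN,
    uwot,
    jsonlite,
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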