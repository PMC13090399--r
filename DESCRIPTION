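Package: densemorph
Title: Dense Surface-Correspondence Geometric Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An almost landmark-free 3D geometric-morphometrics toolkit for
    comparative shape analysis of triangular surface meshes. A reference mesh
    is deformed onto each target specimen by thin-plate-spline landmark
    registration followed by an elastic iterative-closest-point algorithm
    with Gaussian-smoothed displacement fields, producing a sample of meshes
    with identical, corresponding vertices. Corresponding vertices can be
    subsampled by k-means clustering (keeping real surface vertices nearest
    each cluster mean), and the resulting dense coordinates analysed by
    Generalized Procrustes Analysis, shape PCA with out-of-sample projection
    and mean-shape warps, Procrustes and Mahalanobis distances, and static
    allometry. Includes a subsample-size optimization protocol, landmark- and
    correspondence-error quantification, a parametric synthetic cranial-patch
    generator for validation, and a command-line pipeline. Reads and writes
    PLY, OBJ and STL meshes and CSV landmark files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
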