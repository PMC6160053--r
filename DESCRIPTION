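Package: trabecula
Title: Trabecular Architecture Analysis of Porous Skeletal Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying the three-dimensional trabecular
    architecture of porous skeletal microstructure (such as the echinoid
    stereom) from micro-CT subvolumes. Reads 8-bit volumes (TIFF stack or
    NRRD), applies edge-preserving contrast enhancement, band thresholding
    and small-component removal, extracts a one-voxel-thick homotopic
    skeleton, converts it into a spatial graph of nodes and polyline
    segments with distance-transform radii, and computes eight trabecular
    descriptors: chord length, curved length, tortuosity, radius,
    slenderness ratio, inter-trabecular angle, node configuration, and the
    orientation angles theta and phi. Includes subsampled Wilcoxon
    rank-sum comparisons with mean-p reporting, Shapiro-Wilk, moment
    skewness and kurtosis, chi-squared uniformity tests and rose-diagram
    binning, Euler buckling mechanics, an Avizo SpatialGraph ASCII
    importer, and a ground-truthed synthetic trabecular-network generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    generics,
    rlang,
    jsonlite,
    tiff,
    igraph,
    withr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
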