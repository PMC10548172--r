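Package: cardiofiber
Title: Micrometer-Scale Cardiomyocyte Orientation Recovery from Membrane-Stained Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recovering per-voxel cardiomyocyte long-axis
    orientation from three-dimensional membrane-stained image stacks.
    Provides synthetic phantoms with known orientation fields (straight
    tube bundles and helical ventricular-wall annuli), image restoration
    (Richardson-Lucy deconvolution with total-variation regularization,
    patch-dictionary sparse denoising, phase-correlation stitching of
    overlapping fields of view), structure-tensor orientation estimation
    with fractional anisotropy and pseudo low-resolution tensor
    coarsening, cardiac coordinate frames and helix-angle maps derived
    from wall masks, sector-wise transmural profiles with piecewise-line
    fits, and glyph/streamline visualization exports (legacy VTK).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
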