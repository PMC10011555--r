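Package: fiber3d
Title: Multiscale 3D Frangi Enhancement and Fiber Orientation Analysis for
    Fluorescence Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting 3D fiber orientation maps from fluorescence
    microscopy volume images. Implements a scale-normalized 3D Frangi
    vesselness filter with Hessian eigenanalysis for the selective enhancement
    of tubular (myelinated-fiber-like) structures, anisotropic point spread
    function compensation and isotropic resampling, automatic fiber and soma
    masking via minimum cross-entropy (Li) and maximum correlation (Yen)
    thresholding, aggregation of voxel-wise orientations into spherical
    harmonics orientation distribution function (ODF) maps at arbitrary
    super-voxel scales, synthetic phantom generators (cylinders, blobs,
    plates, crossings, fiber stacks), a rotation-based validation harness
    quantifying angular accuracy, and a chunked processing pipeline for
    volumes larger than memory.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    tiff,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
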