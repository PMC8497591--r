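Package: smartscan
Title: Adaptive Smart-Scanning Strategies for Surface-Confined Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for adaptive scan-path planning in
    volumetric fluorescence microscopy of epithelial cell sheets. Generates
    synthetic epithelial phantoms (curved surface, Voronoi cell-contour mesh,
    inhomogeneous background, optional decoy surface and photobleaching),
    estimates the surface of interest from a highly fractional random pre-scan
    (robust background normalization, significance-test bright-point detection,
    windowed RANSAC polynomial fits, biharmonic spline interpolation), and
    executes two light-dose-sparing acquisition strategies against a voxel
    oracle: an exhaustive scan of a thin shell around the estimated surface,
    and an iterative nearest-neighbor propagative scan of cell outlines.
    Includes dose accounting and ground-truth evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    mgcv,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
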