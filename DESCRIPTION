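Package: zpeel
Title: Surface-Guided Peeling and Projection of 3D Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric "peeling" of 3D fluorescence microscopy z-stacks prior
    to 2D projection. A surface of interest is described either by a sphere
    fitted robustly (L1 loss) to Otsu-thresholded foreground voxels, or by a
    2D cubic-spline surface interpolating a small regular grid of user-chosen
    control depths. The volume on one side of the surface (inside/outside the
    scaled sphere, above/below the spline surface) is masked out and the
    remainder reduced to 2D by maximum-intensity projection, so that
    structures on curved tissue layers -- e.g. cell sheets on spherical
    embryos -- can be visualised without being occluded by brighter layers.
    Supports ImageJ-style multi-channel and time-lapse hyperstacks (with
    per-frame sphere fits and temporal interpolation of control points), a
    synthetic two-sheet benchmark volume generator with ground truth, and
    evaluation metrics (RMSE against a known sheet intensity, Dice overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
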