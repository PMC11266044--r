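Package: BrainMosaic
Title: Tile-Based Assembly of Serial Two-Photon Whole-Brain Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs whole mouse-brain image volumes from serial
    two-photon tomography (TissueCyte-style) tile acquisitions. Provides
    flat-field (vignetting) correction by per-channel average-tile profiles,
    lens-distortion calibration from mesh-grid target images (homography plus
    residual bicubic-spline displacement field), inter-tile translation
    estimation by normalized cross-correlation of overlap strips, feathered
    mosaic stitching of tiles into seamless section images, and stacking of
    sections into 3D volumes exported as NIfTI and multiscale OME-Zarr with a
    Neuroglancer viewer URL. A synthetic-acquisition generator with known
    ground truth makes every stage testable end to end without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    tiff,
    jsonlite,
    yaml,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
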