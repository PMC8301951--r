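Package: sphereloc
Title: Automatic Localization of Spherical Fiducial Markers in 3D MRI Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and sub-voxel localization of spherical fiducial
    markers in volumetric MRI data. Implements four complementary detectors
    (bidirectional slice-wise circular Hough transform, signed spherical
    matched-kernel convolution, connected-component analysis with radius and
    roundness filtering, and a determinant-of-Hessian blob detector with
    moment-based k-means candidate filtering), a two-sphere marker-pairing
    model that yields marker position and axis direction, a synthetic phantom
    generator with exact ground truth, and the detection/localization
    evaluation metrics (F1 before/after the marker model, positioning error,
    spacing error, resolution limit, orientation-error bound).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
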