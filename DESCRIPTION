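Package: romvision
Title: Lower-Limb Joint Range of Motion from RGB-D Marker Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures human lower-limb joint range of motion (hip and knee in
    the sagittal plane, hip in the coronal plane) from sequences of paired
    color and depth frames with strip markers on the thigh, calf and seat.
    Implements the pinhole camera model with radial/tangential lens
    distortion, registration of depth pixels into the color camera frame,
    RGB-distance threshold segmentation with 8-connected component labeling,
    median-depth marker sampling, constrained total-least-squares plane and
    line fits, signed joint-angle computation, median-average filtering, peak
    detection and peak-difference validation against reference angle traces.
    Includes a synthetic RGB-D scene generator for a two-link articulated leg
    with ground-truth angles, used to validate the full measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
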