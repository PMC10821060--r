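Package: wristdtw
Title: Movement Quality Classification from a Wrist-Worn IMU via Windowed
    Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Participant-specific classification of upper-limb task-practice
    movement quality (correct versus compensatory or incomplete) from a single
    wrist-worn 9-axis inertial measurement unit. Lab-recorded, therapist-labeled
    reference trials are compared to unlabeled home trials using banded
    multivariate dynamic time warping with a test-anchored projected distance.
    The package implements six-axis orientation filtering and gravity removal,
    per-axis normalization, a statistical method-selection procedure combining
    one-sided Welch tests on distance clusters with leave-one-trial-out
    accuracy, 1-nearest-neighbor quality labeling, confusion-matrix reporting
    with per-movement-type sensitivity, an acceleration-only ablation, and a
    physically consistent synthetic IMU session generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
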