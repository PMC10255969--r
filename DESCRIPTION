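Package: crabgrade
Title: Machine-Vision Quality Grading of River Crabs with a GA-Initialized BP Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quality grading of river crabs (Eriocheir sinensis) from
    paired back/abdomen images and a measured weight. Provides 8-bit image
    preprocessing (weighted-average grayscale conversion, median filtering),
    extraction of the four grading features (gender by rotation/scale template
    matching of the abdominal umbilicus, carapace length by Hough-gradient
    circle detection with pixel calibration, condition-factor fatness, and
    mean shell gray), a real-coded genetic algorithm that searches initial
    weights and thresholds for a single-hidden-layer backpropagation network,
    momentum gradient training with early stopping, hidden-node selection by
    training mean squared error, and an evaluation pipeline over repeated
    random 70/30 splits. A synthetic specimen generator with known ground
    truth stands in for the camera and load-cell hardware so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
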