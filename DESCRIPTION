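Package: beescan
Title: Tracking and Analysis of Bumblebee Scanning Flights in Pattern
    Discrimination Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Video tracking and behavioural analysis of individual
    bumblebees flying in a discrimination arena. Provides background
    subtraction and blob tracking with moment-based body-orientation
    estimation, pixel-to-metric calibration, flight-kinematics extraction,
    landing detection via a K-means speed threshold, segmentation of
    stimulus inspections and scanned-region classification, and the
    accompanying statistics: chi-square tests of first choices, Wilcoxon
    tests, binomial mixed models of learning curves, and two-component
    Gaussian-mixture fits to body-yaw distributions. A synthetic flight
    and video generator with full ground truth makes every stage of the
    pipeline testable without original recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    lme4,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
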