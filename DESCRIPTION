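Package: placingbricks
Title: Instrumented Placing Bricks Test Analysis from Wrist Gyroscope Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the instrumented Placing Bricks fine-motor assessment.
    Detects task events (Initial Grasping, Grasping End, Initial Placing,
    Placing End) from wrist-worn gyroscope recordings via a signed-peak
    algorithm on the low-pass filtered sum of the longitudinal and
    antero-posterior angular-velocity components, segments trials into
    grasp/flight/place/cycle phases, quantifies phase duration and its
    short- and long-term variability (Poincare SD1/SD2), validates detections
    against video-derived reference annotations (sensitivity, positive
    predictive value, Bland-Altman agreement, Pearson correlation, reliability
    gating), runs nonparametric group comparisons, and simulates trials with
    known ground-truth events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
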