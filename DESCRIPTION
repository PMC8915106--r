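Package: reachkin
Title: Kinematic Analysis of Upper-Limb Reaching Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing and statistical analysis of two-channel goniometric
    recordings of an eight-phase upper-limb reaching protocol. Provides
    zero-phase Butterworth smoothing and cubic-spline resampling of angular
    position signals, forward-Euler differentiation to velocity, acceleration
    and jerk, velocity-threshold segmentation of the record into submovements,
    extraction of thirteen kinematic parameters per submovement, and a
    normality-routed two-group comparison layer (Shapiro-Wilk, Levene,
    Student/Welch t, Mann-Whitney U) with a p-value heatmap export. A
    synthetic-recording simulator with healthy and parkinsonian motion models
    and annotated ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
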