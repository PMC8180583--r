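Package: gaitgaze
Title: Gaze Behavior Analysis During Real and Virtual Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for mobile eye-tracking recordings collected
    while walking through real and virtual environments. Provides readers and
    writers for tabular gaze streams, sector (terrain) segmentation,
    calibration-grid polynomial mapping and drift estimation from validation
    grids, robust descriptive gaze statistics (median/IQR summaries, T-shape
    ratios, direction and velocity histograms, heatmaps), velocity-threshold
    saccade detection with median-based noise estimation, correlation-based
    horizon tracking for eye-in-world referencing, trapezoidal area-of-interest
    dwell-time accounting, and within-subject inference (paired t-tests and
    2x3 repeated-measures ANOVA with Mauchly's sphericity test and
    Greenhouse-Geisser correction). A synthetic-session generator produces
    gaze recordings with known ground truth so every stage of the pipeline can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
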