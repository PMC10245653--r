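Package: astroca
Title: Astrocyte Calcium Dynamics and Freely-Moving Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline relating cortical astrocyte calcium dynamics,
    recorded by fiberscope imaging in freely moving mice, to spontaneous
    behavior. Provides baseline (F0) estimation by kernel-density mode
    tracking with modified Akima interpolation, dF/F computation,
    dual-wavelength hemodynamic correction, calcium transient detection by
    z-scored peak finding with Gaussian fit confirmation, keypoint-based
    behavioral event detection (locomotion, quiescence-to-active
    transitions, rearing, object-directed exploration, sleep, circadian
    structure), event-aligned population statistics (triggered averages,
    latency Gini/Lorenz and coefficient of variation, Fano-factor epochs,
    synchronization index, bootstrap Bayesian activeness posterior),
    PCA plus Gaussian-mixture clustering of peri-event responses, and a
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    tiff
Config/testthat/edition: 3
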