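Package: pfdyn
Title: Lap-by-Lap Place-Field Dynamics from Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of hippocampal place-field dynamics from two-photon
    calcium imaging of head-fixed mice on virtual linear tracks. Detects
    significant calcium transients with a false-positive-controlled
    amplitude/duration filter, defines place fields on lap-by-bin activity
    matrices with a bootstrap significance test, and quantifies lap-wise
    field dynamics: center-of-mass drift regressions, population backward
    shifting relative to a reference lap, onset-lap detection, spatial
    precision, skewness and width, within- and across-day spatial map
    stability, and first-lap position decoding with a Gaussian naive Bayes
    decoder. Includes a synthetic session generator with known ground truth
    (GCaMP6f-like transients, configurable field center, width, onset lap,
    per-lap drift, reliability and across-day fate) so every stage is
    testable end to end, and estimation statistics (bootstrapped mean
    differences with percentile confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
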