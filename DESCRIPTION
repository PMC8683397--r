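Package: fetalstress
Title: Maternal-Fetal Heart Rate Coupling and Self-Supervised ECG Stress Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting chronic prenatal stress from maternal and
    abdominal electrocardiograms. Implements bivariate phase-rectified signal
    averaging (BPRSA) of maternal and fetal heart-rate series and the Fetal
    Stress Index (FSI) derived from it, a signal-quality-driven preprocessing
    chain (SQI filtering, resampling to 256 Hz, 10-s segmentation), a
    self-supervised transformation-recognition convolutional network for
    learning ECG representations, frozen-trunk affect heads for stress
    classification and biomarker regression (hair cortisol, FSI, PDQ, PSS-10),
    a within-subject five-fold evaluation protocol with the full
    classification/regression metric panel, and a synthetic abdominal-ECG
    cohort generator with a tunable maternal-to-fetal coupling ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
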