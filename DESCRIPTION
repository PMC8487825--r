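Package: sonovas
Title: Lower-Extremity Arterial Ultrasound Image Processing and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing B-mode ultrasound images of the lower-extremity
    arteries and the clinical measurements derived from them. Provides a
    non-local means speckle denoiser with a Gaussian-weighted patch distance
    and restricted search window, block-based first-order and gray-level
    co-occurrence matrix (GLCM) texture features, the standard clinical vessel
    metrics (intima-media thickness classification, plaque calling,
    percent-diameter stenosis rate and ordinal grading with worst-lesion
    reduction), and a three-group cohort comparison layer (mean +/- SD
    summaries, one-way ANOVA, chi-square incidence tests). Because clinical
    images and patient tables of this kind are rarely shareable, the package
    ships a synthetic-data module: speckle-corrupted vessel phantoms with
    known ground truth and simulated cohorts calibrated to published group
    contrasts, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
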