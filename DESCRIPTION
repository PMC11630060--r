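Package: lqconvert
Title: Linear-Quadratic Survival Modelling and Isoeffect Dose Conversion
    for Hypofractionated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the linear-quadratic (LQ) cell-survival model to
    clonogenic-assay data, converts fractionated radiotherapy regimens to
    equivalent single doses both by biologically-effective-dose (BED)
    isoeffect algebra and by inversion of the fitted survival curve, and
    quantifies the discrepancy between the two as a calculated/measured
    (C/M) percentage. Includes EQD2 computation, alpha/beta sensitivity
    analysis, and a synthetic-data module that simulates colony-count
    assays under LQ or LQ-with-linear-tail truth models plus a toy
    xenograft growth simulator, so that parameter recovery and the
    high-dose overestimation mechanism can be studied end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
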