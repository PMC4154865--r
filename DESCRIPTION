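Package: crcmarkers
Title: Combined Fecal-Marker Prediction Models for Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating diagnostic prediction models
    that combine a binary fecal occult blood test (FOBT) with a continuous
    fecal calgranulin B (CALB) western-blot measurement. Implements
    rank-transform logistic modelling with a rank-lookup scoring table for
    future subjects, empirical ROC analysis with partial AUC over a
    high-specificity range, the DeLong paired test for correlated AUCs,
    category-free reclassification improvement and NRI, leave-one-out
    cross-validation with per-fold cutoff selection at a target specificity,
    exact-binomial diagnostic-accuracy assurance and sample-size
    calculations, and a calibrated synthetic case-control cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
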