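Package: cpqsar
Title: QSAR Classification and Mondrian Conformal Prediction for
    Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation of ChEMBL-style bioactivity tables into per-target
    active/inactive modelling sets, Morgan-fingerprint featurization,
    class-weighted Random-Forest QSAR models and Mondrian conformal
    predictors built under a shared repeated-split protocol, and the
    evaluation framework needed to compare the two arms: sensitivity,
    specificity and correct classification rate with both/empty-aware
    variants, per-class conformal validity, Tanimoto similarity
    diagnostics, and temporal validation across database releases.  A
    synthetic-data generator with known ground truth makes the whole
    pipeline exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    yaml,
    withr
Config/testthat/edition: 3
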