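Package: oxrecal
Title: External Validation and Recalibration of OxRec-Style Recidivism Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating and recalibrating clinical
    prediction models of the OxRec family, which estimate the probability of
    violent reoffending within a fixed horizon after prison release as
    1 - S^exp(lambda * LP). Provides a risk scoring engine over configurable
    coefficient sets with mean-imputation offsets for predictors unavailable
    in the validation setting; a performance-metric suite (Brier score, AUC
    with DeLong confidence intervals, calibration-in-the-large, calibration
    slope, expected-to-observed ratio, decile calibration bins, and threshold
    classification tables with Wilson intervals); an incremental
    model-updating ladder on the complementary log-log scale (simple
    validation, baseline-risk update, single multiplicative recalibration,
    selective re-estimation of one predictor); and a synthetic cohort
    generator with configurable predictor marginals and injectable
    miscalibration for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
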