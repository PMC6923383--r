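Package: modspanel
Title: Stability-Selected Biomarker Panels for Post-Trauma Multi-Organ
    Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of candidate biomarker panels that
    predict multi-organ dysfunction syndrome (MODS) from early post-trauma
    immunological feature tables. Implements the full analysis pipeline:
    cohort preprocessing (missingness filtering, minimum-value imputation,
    autoscaling, time-point integration), dual LASSO/Elastic-Net stability
    selection with repeated 75/25 subsampling and cross-validated penalty
    tuning, appearance-frequency thresholding at an upper quantile, and
    permutation-calibrated AUC assessment of candidate panels via repeated
    65/35 resampling of an unpenalized logistic model. A seeded synthetic
    cohort generator with planted effects and ground truth makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
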