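Package: pandagrowth
Title: Lifespan Weight-for-Age Modelling for Captive Giant Pandas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building weight-for-age reference charts for captive
    giant pandas (Ailuropoda melanoleuca) from longitudinal zoo weighing
    records. Provides a synthetic-cohort simulator with known ground truth,
    a feeding-status calibration step that removes post-feeding weight bias
    by two-cluster splitting within each month of age, age-stratified
    gradient-boosted growth models with cross-validated comparison against
    other tree ensembles, bootstrap percentile confidence bands for daily
    weight predictions across the full lifespan, and nonparametric tests of
    seasonal, reproductive-period and sex differences in adult weight and
    growth velocity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    xgboost,
    randomForest,
    ranger,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
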