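Package: bcproxy
Title: Input-Adaptive Proxy Imputation for Air-Quality Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds "virtual sensor" regression proxies for gappy air-quality
    time series such as black carbon. Candidate predictors are screened by
    Pearson correlation, all subsets of up to three inputs are fitted by
    iteratively reweighted least squares with the Tukey bisquare weight,
    models with inflated variance (VIF) or non-normal residuals (Lilliefors
    test) are rejected, and the survivors are ranked by adjusted R-squared,
    MAE and RMSE. Gaps in the target series are then filled by cascading
    through the ranking: each missing hour is predicted by the best-ranked
    model whose inputs are available at that hour. Includes hourly averaging,
    wind-vector decomposition, log transforms, thermal-season and
    workday/weekend classification, a synthetic-data generator for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    car,
    optparse
Config/testthat/edition: 3
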