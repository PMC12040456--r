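Package: phycofactor
Title: Environmental-Factor Importance and Condition Optimization for Microalgal Cultivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing one-factor-at-a-time (OFAT) microalgal
    cultivation experiments: a synthetic-data generator with planted response
    surfaces for five algal genera, MANOVA with the four classical multivariate
    test statistics (Wilks, Pillai, Hotelling-Lawley, Roy), a composite
    model-selection score that balances train/validation R-squared against
    error magnitude, seeded k-fold cross-validation and grid search over a
    roster of regression families, impurity-based environmental-factor
    importance ranking, and optimal cultivation-condition reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
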