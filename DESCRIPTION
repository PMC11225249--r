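Package: fuzzylogit
Title: Fuzzy Logistic Regression for Imbalanced and Separated Binary
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification with fuzzy logistic regression based on
    triangular fuzzy numbers (TFNs) for coefficients, inputs, and outputs.
    Provides TFN arithmetic and alpha-cuts, fuzzification of crisp responses
    and predictors with a controlled degree of fuzziness, a bounded random
    search estimator that selects its optimization measure by lowest
    variation, fuzzy threshold classification, and center-of-gravity
    defuzzification with odds-ratio interpretation. Also includes
    complete-separation diagnostics based on maximum likelihood coefficient
    trajectories, an imbalance-aware evaluation suite (confusion-matrix
    metrics, SMOTE oversampling, repeated stratified cross-validation,
    Friedman and Nemenyi model comparison), and a synthetic clinical-data
    generator with controlled class imbalance and separation.
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
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
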