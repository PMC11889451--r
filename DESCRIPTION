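Package: missdiag
Title: Diagnosis of Missing-Data Mechanisms and Benchmarked Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising and handling missing values in rectangular
    numeric data. Diagnoses the missingness mechanism: Little's MCAR chi-square
    test backed by EM estimation of the mean and covariance under multivariate
    normality (gated by a Henze-Zirkler multivariate normality check), followed
    by feature-wise MAR-versus-MNAR likelihood-ratio tests on nested logistic
    models of the missingness indicator. Imputes by simple statistics, k-nearest
    neighbours, iterative round-robin regression with pluggable learners, and
    multiple imputation with Rubin pooling. Imputation quality is assessed by
    plausibility checks and a mask-and-score comparison protocol, and seeded
    generators produce synthetic MCAR/MAR/MNAR benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    ranger,
    xgboost
Config/testthat/edition: 3
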