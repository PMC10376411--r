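Package: clpnet
Title: Cross-Lagged Panel Network Analysis of Symptom Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for cross-lagged panel networks (CLPN)
    of questionnaire symptom data measured at two waves. Provides cohort
    screening and descriptive tables, node-wise LASSO estimation of directed
    cross-lagged networks with covariate adjustment, in/out expected-influence
    centralities, EBIC-selected graphical-lasso cross-sectional networks,
    a paired permutation network comparison test, case-dropping and
    nonparametric bootstrap machinery with correlation-stability
    coefficients, matrix-correlation sensitivity checks, and a synthetic
    two-wave Likert panel generator with known ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
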