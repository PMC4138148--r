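Package: bllasso
Title: Group Lasso Logistic Regression for Elevated Blood Lead Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening questionnaire and biomarker risk factors of
    elevated childhood blood lead levels (BLL >= 10 ug/dL), as used in
    population studies around informal e-waste recycling sites. Provides a
    seeded synthetic survey generator with log-normal blood lead margins and a
    logistic outcome mechanism; descriptive epidemiology (chi-square tables,
    log-scale t-tests, Mann-Whitney comparisons, covariance-adjusted area
    contrasts); a from-scratch group Lasso logistic regression solver using
    group descent over orthonormalized dummy-variable groups, with
    cross-validated deviance tuning of the penalty; and stability validation
    by bootstrap selection frequencies and permutation nulls at multiple
    sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
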