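Package: deltami
Title: Delta-Based Controlled Multiple Imputation Sensitivity Analysis for
    Repeatedly Measured Trial Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the sensitivity of longitudinal clinical
    trial conclusions to missing outcome data.  Provides a simulator for
    trials with a weekly continuous outcome (random intercept/slope plus
    spatially correlated within-participant errors), parametric logistic
    missingness mechanisms spanning MCAR, MAR and MNAR, a cross-sectional
    linear model and a linear mixed model with AR(1) residual correlation
    for the treatment policy contrast, multiple imputation by chained
    equations with predictive mean matching pooled by Rubin's rules, a
    delta-based ("tipping point") sensitivity sweep in which imputed values
    are shifted by a fraction of the residual standard deviation, the
    sensitivity-interval-of-rejection and -concordance summary metrics, and
    a replication driver for simulation studies of all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    mvtnorm,
    optparse
Config/testthat/edition: 3
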