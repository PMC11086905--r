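Package: sfirank
Title: Questionnaire Short-Form Construction via Cross-Validated Shapley
    Feature Rankings
Version: 0.1.0
Authors@R:
    person("sfirank", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reducing a long psychometric scale to a short form by
    ranking items on their predictive contribution to a binary clinical
    outcome. Implements repeated stratified k-fold cross-validation of an
    L2-penalised logistic model, exact, linear and kernel Shapley-value
    attribution, aggregation of per-fold top-k item sets into a frequency
    statistic (SHAP Feature Importance, SFI), comparison of rankings to a
    reference short form by criterion distribution, and quota-constrained
    short-form assembly. Includes a synthetic-cohort generator (correlated
    latent factors, graded-response ordinal items, logistic outcomes at a
    target prevalence) so the full pipeline is testable without access to
    the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
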