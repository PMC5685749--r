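Package: dfsurro
Title: Two-Stage Meta-Analytic Validation of Disease-Free Survival as a
    Surrogate for Overall Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for validating a candidate surrogate
    endpoint (disease-free survival) against a true endpoint (overall
    survival) across a meta-analysis of trials. Reconstructs per-trial log
    hazard ratios from published summaries (direct HR with confidence
    interval, p-value with event counts, or digitized Kaplan-Meier curves
    with optional at-risk tables), quantifies individual-level association
    with a Clayton-copula bivariate survival model fitted by censored-data
    pseudo-likelihood, fits the trial-level weighted regression of the
    treatment effect on the true endpoint on the effect on the surrogate,
    derives the surrogate threshold effect from estimation-error-adjusted
    prediction limits, and assesses predictive accuracy by leave-one-out
    cross-validation. A synthetic meta-analysis generator with known
    surrogacy structure provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
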