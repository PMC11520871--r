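Package: metaburden
Title: Random-Effects Meta-Analysis of Prevalence and Population Burden
    Projection for Mass-Trauma PTSD
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for projecting the expected caseload of post-traumatic
    stress disorder (PTSD) across a population stratified by intensity of
    traumatic exposure. Provides an auditable study-screening stage
    (clinical-assessment preference, timing and point-prevalence rules,
    help-seeking exclusion, a questionnaire correction factor), a
    self-contained random-effects meta-analysis of prevalence proportions
    (DerSimonian-Laird and REML between-study variance, Q and I-squared
    heterogeneity, confidence and prediction intervals), derivation of
    estimates for unreviewed strata by borrowing or averaging, projection
    of expected case counts with uncertainty ranges, and a synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
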