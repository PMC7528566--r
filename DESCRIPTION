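Package: twinpath
Title: Twin Modeling, Eating-Behavior Patterns, and Polygenic Mediation
Version: 1.0.0
Authors@R:
    person("Elena", "Varga", email = "elena.varga@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis chain for classical twin studies of eating
    behavior and obesity: varimax-rotated principal-component derivation of
    eating-behavior patterns, univariate ACE/ADE/AE and bivariate Cholesky
    variance decomposition by maximum likelihood, partial correlations and
    single-mediator structural models linking polygenic scores, behavior
    patterns, and obesity measures, with family-clustered robust errors and
    bias-corrected bootstrap confidence intervals. Includes a synthetic
    twin-cohort generator with known variance-component, factor, and
    mediation structure so every stage can be validated against ground
    truth, plus a command-line interface for pipeline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
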