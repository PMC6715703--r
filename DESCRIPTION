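Package: thermolimits
Title: Robust Threshold Analysis for Method-of-Limits Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for robust analysis of method-of-limits detection
    thresholds, built for thermal (warm/cool) psychophysics in clinical
    group comparisons. Per-subject summaries use the Harrell-Davis
    quantile estimator and Gini's mean difference; group comparisons use
    Cliff's delta with asymmetric confidence intervals, two one-sided
    equivalence tests, and Monte-Carlo power analysis; rank correlations
    are tested on the Fisher-z scale with equivalence bounds and Zou
    difference intervals; and continuous outcomes are modelled with
    semi-parametric proportional-odds cumulative probability models,
    best-subset selection by BIC weights, predictive-mean-matching
    multiple imputation, and Rubin's-rules pooling. A synthetic cohort
    generator emulates right-skewed thresholds with coupled
    trial-to-trial noise so the full pipeline is testable without
    participant data.
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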