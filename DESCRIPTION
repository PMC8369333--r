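Package: bayesequiv
Title: Bayesian Equivalence Testing for Two-Sample Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian equivalence (interval-null) tests for the two-sample
    setting on the standardized effect size: interval Bayes factors under
    Jeffreys-Zellner-Siow Cauchy priors (point-null, overlapping,
    non-overlapping and hybrid hypothesis models) and region-of-practical-
    equivalence (ROPE) decisions based on highest-posterior-density and
    support intervals. Includes Monte-Carlo estimation of type I error,
    power and inconclusive rates across sample sizes, prior scales and
    equivalence regions, and a selection procedure that recommends the
    narrowest equivalence region compatible with objective criteria
    (attainable sample size, maximum type I error, minimum power, elicited
    prior). A frequentist two-one-sided-tests (TOST) procedure is provided
    for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
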