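Package: pafbias
Title: Population Attributable Fractions Under Confounding and Selection Bias
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of population attributable fractions (PAF) from
    stratified closed-cohort count data using both the prevalence-of-deceased
    (Miettinen-type) and prevalence-of-exposed (Levin-type) formulas, their
    multi-level-exposure extensions, weighted-sum standardization over
    confounder strata, and counterfactual true-PAF computation. Includes a
    synthetic-cohort generator with configurable confounding and endogenous
    (collider) selection into the sample, a from-scratch discrete-time
    survival fitter with complementary log-log link and optional
    Gauss-Hermite random intercepts, and pipelines that contrast how the two
    PAF formulas behave when risk ratios are biased by confounding or by
    selection on unobserved health.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
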