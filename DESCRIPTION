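Package: twinrisk
Title: Twin-Study Analysis of Age-Dependent Disease Risk Under Competing
    Risks
Version: 0.1.0
Authors@R:
    person("twinrisk", "maintainers", email = "maintainers@twinrisk.org",
           role = c("aut", "cre"))
Description: Tools for the classical twin design applied to an
    age-dependent dichotomous endpoint observed under right censoring and
    the competing risk of death.  Implements liability-threshold
    biometric models (saturated, ACE, ADE, AE, CE, DE) with inverse
    probability of censoring weights, maximum-likelihood tetrachoric
    correlations with a high-accuracy bivariate normal orthant routine,
    pair-level concordance statistics, Aalen-Johansen cause-specific
    cumulative incidence with delayed entry, age-indexed proband-wise
    concordance and heritability curves, and a twin-cohort simulator
    with known additive genetic (A), dominance (D), shared environment
    (C) and unique environment (E) variance structure for validation.
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
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
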