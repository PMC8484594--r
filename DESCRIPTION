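Package: conjointvax
Title: Conjoint Analysis of Vaccine-Acceptance Survey Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machinery for randomized vignette (conjoint) experiments on
    vaccine acceptance: a constrained, blocked randomization engine over a
    five-dimension attribute catalog (producer, efficacy disclosure,
    endorser, distributor, community uptake) in which "unspecified" levels
    are available only in the first round; analytic design-based inverse
    probability of treatment weights; average marginal component effect
    (AMCE) estimation by weighted least squares with respondent and
    block-by-round-by-country fixed effects absorbed and cluster-robust
    (CR1) inference; heterogeneous-effect estimation with trust moderators;
    marginal means; randomization, attrition, and first-round-only
    diagnostics; and a fully specified potential-outcomes simulator with
    screening emulation so the whole pipeline is testable without fielded
    data.
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
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
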