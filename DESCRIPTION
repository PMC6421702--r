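Package: mhtriage
Title: Safety Protocols and Referral Triage for Autonomous e-Mental-Health Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision engine for patient-safety protocols in autonomous
    e-mental-health (AEMH) systems: two-step risk detection with questionnaire
    gating and a duration/severity/progression referral rule, a consent-gated
    auto-referral workflow state machine, and a stance-by-severity dialogue
    policy that selects and renders a referral strategy (facilitate, persuade,
    or accept rejection). Also provides scoring for the accompanying
    instruments (ISI, feeling-of-being-heard scale, Cronbach's alpha), a
    synthetic generator for the 3x3x3 within-subject referral-strategy
    experiment, and the matching inference pipeline: random-intercept linear
    mixed models fit by maximum likelihood, cumulative-link mixed models via
    Gauss-Hermite quadrature, likelihood-ratio model ladders, and chi-square
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
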