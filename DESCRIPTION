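Package: exposcan
Title: Exposome-Wide Association Scanning and Model Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exposome-wide association studies (ExWAS) of a
    continuous outcome against thousands of correlated questionnaire-derived
    exposures. Implements false-discovery-rate univariable screening with a
    variable p-value criterion, chained-equation multiple imputation with
    Rubin pooling, domain-specific and combined stepwise and best-subset
    model reduction under a single significance criterion, and post-model
    probes: pairwise interaction scanning and reduction, quadratic
    non-linearity tests, mediator attenuation, prevalence-shift translation,
    proportional-odds and factor-space sensitivity refits, and a CHAID-style
    regression tree. A synthetic-exposome generator with a Gaussian-copula
    correlation structure, planted effects and configurable missingness
    supports desk-scale validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
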