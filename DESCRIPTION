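Package: cureaudit
Title: Mixture Cure Models for Auditing Diagnostic-Timing Bias in Clinical
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying algorithmic bias in diagnosis-probability
    estimation when diagnostic timing differs between groups. Simulates
    two-group right-censored cohorts with a cured/susceptible mixture
    structure, fits a mixture cure model (logistic incidence, log-normal
    latency) by direct maximum likelihood, compares it against logistic
    regression, Cox proportional hazards and log-normal accelerated failure
    time models across administrative censoring horizons, and summarises
    per-group predicted diagnosis probabilities with bootstrap confidence
    intervals. Also provides a synthetic administrative-claims emulator and
    a two-code computable-phenotype cohort builder mirroring claims-based
    study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
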