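Package: lgcmtrial
Title: Latent Growth Curve Analysis of Two-Arm Longitudinal Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-arm randomized trials with repeated
    questionnaire outcomes using latent growth curve models on a
    log-transformed time basis. Provides full-information maximum likelihood
    (FIML) estimation under wave-wise missingness, Wald tests and confidence
    intervals, a random-walk Metropolis posterior sampler with Gelman-Rubin,
    WAIC and leave-one-out diagnostics, standardized mean differences of
    change scores, baseline comparison statistics, questionnaire scoring for
    depression and social anxiety scales, and a seeded generator of synthetic
    trials with heavy-tailed behaviour counts for validation and power work.
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
    lme4,
    ggplot2,
    withr
Config/testthat/edition: 3
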