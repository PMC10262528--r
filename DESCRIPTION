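Package: frailtytrials
Title: Cumulative-Deficit Frailty Indices and Outcome Associations in Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cumulative-deficit frailty indices from clinical-trial
    baseline tables (physical and physical+cognitive variants), summarises
    their distributions parametrically (lognormal, gamma, Weibull and
    generalised gamma fits compared by Kolmogorov-Smirnov statistic), and
    estimates per-trial associations between frailty and serious adverse
    events (Poisson regression with a person-time offset) and trial
    attrition (logistic regression), pooling coefficients across trials by
    random-effects meta-analysis. Includes a latent-trait synthetic trial
    generator so the full pipeline can be exercised and validated without
    access-restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    flexsurv,
    fitdistrplus,
    metafor
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
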