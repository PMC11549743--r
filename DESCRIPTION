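Package: immortaltime
Title: Simulation of Immortal Time Bias under Time-Varying Hazards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts with a dichotomous time-varying exposure
    (at most one unexposed-to-exposed switch) and Weibull event times, and
    quantifies the bias of the unadjusted Poisson rate-ratio estimator when
    person-time is classified correctly but the baseline hazard trends over
    follow-up. Provides the immortal-time-correct bookkeeping layer
    (counting-process episodes, follow-up splitting, person-time rate
    tables), four estimators (closed-form and fitted Poisson rate ratio,
    piecewise-exponential Poisson, Cox regression with a time-varying
    covariate, Kaplan-Meier), and a replicate engine with parameter sweeps
    over the hazard shape, the true exposure effect, and the prevalence of
    and time to exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
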