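Package: ldlsim
Title: Residual Cardiovascular Risk Simulation for LDL-C Treatment Goals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the residual 10-year cardiovascular risk of secondary-
    prevention ASCVD patients under alternative LDL-C treatment goals.
    Provides a seeded synthetic-cohort generator calibrated to published
    marginal summaries (quantile-matched shifted-lognormal LDL-C, stratified
    covariate prevalences, lipid-lowering-therapy mix), a REACH-style
    20-month recurrent-event risk equation with constant-hazard horizon
    conversion, per-patient LDL-C goal-gap computation, Monte-Carlo scaling
    of the rate ratio per 39 mg/dl LDL-C reduction into relative and
    absolute risk reductions, and stratified median/IQR reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
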