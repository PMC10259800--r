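Package: dbdcwtp
Title: Double-Bounded Dichotomous Choice Contingent Valuation of
    Willingness to Pay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing double-bounded dichotomous
    choice (DBDC) contingent-valuation surveys of willingness to pay (WTP),
    as used in health economics to value vaccination programmes. Provides
    Krejcie-Morgan sample-size and largest-remainder stratum allocation,
    a DBDC bid-schedule type with follow-up rule validation, a synthetic
    respondent generator with correlated bivariate-normal latent WTP,
    descriptive response tabulation with chi-square screening and
    variance-inflation diagnostics, univariate probit maximum likelihood
    with sandwich covariance, a seemingly-unrelated bivariate probit
    estimator with latent error correlation and a Wald test, closed-form
    mean WTP from fitted coefficients, and Krinsky-Robb simulated
    confidence intervals with achieved significance levels.
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
    pracma,
    withr
Config/testthat/edition: 3
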