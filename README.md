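# dbdcwtp

Contingent valuation with the **double-bounded dichotomous choice (DBDC)**
format, for health-economics applications such as pricing a hand, foot and
mouth disease (HFMD) vaccination programme.  In a DBDC survey each
respondent sees an initial price bid P1 (MYR 100–400 in steps of 50 by
default) and answers yes/no; a yes raises the follow-up bid by MYR 50, a no
lowers it.  The two answers bound the respondent's latent willingness to
pay (WTP) in one of four intervals (YY, YN, NY, NN), and the package
estimates the WTP distribution from those bounds.

The core model is a pair of latent valuations

    z1* = x'b1 + e1,   z2* = x'b2 + e2,   (e1, e2) ~ BVN(0, 1, rho)

estimated as a **seemingly-unrelated bivariate probit** by maximising
`sum log Phi2(q1 x'b1, q2 x'b2; q1 q2 rho)` with `q = 2z - 1`, where
`Phi2` is the bivariate normal CDF (an accurate quadrature kernel is part
of the package).  Mean WTP follows the closed form
`-xbar' b_nonbid / b0` with `b0` the bid coefficient, and its confidence
interval comes from the **Krinsky–Robb** parametric bootstrap (10,000
multivariate-normal parameter draws, percentile interval, achieved
significance level for H0: WTP <= 0).

The package also covers the surrounding survey workflow: Krejcie–Morgan
sample size, largest-remainder allocation across strata, sample doubling,
MYR/USD conversion, respondent CSV schema with follow-up-rule validation,
effects coding of categorical covariates, response tabulation, chi-square
association screening, VIF diagnostics, a univariate (single-bounded)
probit with robust covariance, and a synthetic respondent generator with
correlated bivariate-normal latent WTP for testing every stage without
access to raw survey data.

## Worked example

```r
library(dbdcwtp)

cfg <- synthetic_config(n = 390, seed = 20200113)   # defaults: latent mean
d   <- generate_respondents(cfg)                    # 400, sigma 300, rho 0.7
tabulate_responses(d)
#>  Initial bid     Yes-Yes     Yes-No     No-Yes      No-No Obs
#>        RM100  36 (66.7%)  6 (11.1%)  8 (14.8%)   4 (7.4%)  54
#>        RM150  38 (63.3%)  6 (10.0%)   5 (8.3%) 11 (18.3%)  60
#>        ...
#>        Total 210 (53.8%) 56 (14.4%) 45 (11.5%) 79 (20.3%) 390

response_correlation(d$z1, d$z2)
#> [1] 0.4179071

ds1 <- design_matrix(d, bid = "bid1", covariates = "education")
ds2 <- design_matrix(d, bid = "bid2", covariates = "education")
fit <- fit_bivariate_probit(ds1, ds2, d$z1, d$z2)
summary(fit)
#> Seemingly-unrelated bivariate probit (n = 390, logLik = -446.242, robust SEs)
#>                   Estimate Std. Error z value Pr(>|z|)
#> eq1:(Intercept)  1.1267014  0.1959103   5.751 8.87e-09 ***
#> eq1:bid1        -0.0025266  0.0006768  -3.733 0.000189 ***
#> ...
#> eq2:bid2        -0.0031761  0.0006546  -4.852 1.22e-06 ***
#> rho = 0.748 (SE 0.061)
#> Wald test rho = 0: Chi2(1) = 151.93, p = 6.556e-35

krinsky_robb(fit, equation = 2, seed = 20200113)
#> Krinsky-Robb WTP estimate
#>   plug-in mean WTP: MYR 394.25 (USD 87.52)
#>   draws: mean 400.89, median 394.60 (10000 used, 0 discarded)
#>   95% CI: [345.44, 494.40]
#>   ASL (H0: WTP <= 0): 0.000
```

Reading the output: the negative bid coefficients say demand falls with
price; `rho = 0.748` is the estimated correlation of the latent errors
across the two questions (the raw 0.42 response correlation is a
different, smaller quantity), and the Wald test rejects independence, so
the joint model is warranted.  The equation-2 ("double-bounded") mean WTP
of MYR 394 recovers the generator's true latent mean of 400 within its
interval; the ASL of 0 says no parameter draw produced a non-positive
WTP.  Survey-design arithmetic is equally direct:

```r
krejcie_morgan(6509400)        # 384 respondents required
double_sample(384L)            # 768 distributed questionnaires
myr_to_usd(394.00)             # 87.47
```

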