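---
title: "Double-bounded dichotomous choice valuation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-bounded dichotomous choice valuation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbdcwtp)
```

## The elicitation format and the latent model

In a double-bounded dichotomous choice (DBDC) survey each respondent is
shown an initial price bid $P_1$ for the good being valued (here, a
two-dose course of HFMD vaccination) and answers yes or no.  A yes is
followed by a raised bid $P_2 = P_1 + \delta$, a no by a lowered bid
$P_2 = P_1 - \delta$; the default schedule is $P_1 \in \{100, 150, \dots,
400\}$ MYR with $\delta = 50$ MYR.  The two answers $(z_1, z_2)$ bound the
respondent's willingness to pay (WTP) in one of four intervals:

| pattern | interval |
|---------|----------------------|
| YY | $[P_2, \infty)$ |
| YN | $[P_1, P_2)$ |
| NY | $[P_2, P_1)$ |
| NN | $[\text{floor}, P_2)$ |

For any bid pair the four intervals partition $[\text{floor}, \infty)$;
`wtp_bounds()` materialises them.  The lower truncation for the NN group
is a genuinely open choice — a refusal of the lowest follow-up bid is
compatible with any smaller WTP, including a negative one.  The package
defaults to `floor = 0` (a negative WTP for a voluntary vaccine has no
economic interpretation here) and accepts `floor = -Inf` for users who
prefer the untruncated convention.

The behavioural model is a pair of latent valuations
$$z_k^{*} = x'\beta_k + \varepsilon_k, \qquad k = 1, 2,$$
with $(\varepsilon_1, \varepsilon_2)$ jointly normal, unit-free after
probit scaling, and correlated with coefficient $\rho$.  The respondent
answers yes to question $k$ when $z_k^{*} > 0$ once the bid is moved into
the index, i.e. $z_k = \mathbf 1\{\mathrm{WTP}_k \ge \text{bid}_k\}$.
The two equations are *seemingly unrelated*: no cross-equation parameter
restrictions are imposed, and they are tied together only through $\rho$.

## Estimation

`fit_probit()` is the single-bounded estimator: univariate probit maximum
likelihood of the first response on the start bid and covariates, by
Newton–Raphson with step-halving on the globally concave log-likelihood,
iterated until the score norm is below $10^{-8}$.  Starting values come
from an ordinary least-squares fit of the latent-scale transform
$1.6449\,(2z-1)$; because the likelihood is concave the start affects only
the iteration count.  Both the classical covariance (inverse observed
information) and the heteroscedasticity-robust sandwich
$A^{-1} B A^{-1}$ (with $A$ the observed information and $B$ the summed
outer products of per-observation scores) are returned.

`fit_bivariate_probit()` maximises
$$\ell(\beta_1, \beta_2, \rho) = \sum_i \log
  \Phi_2\!\left(q_{1i}\,x_{1i}'\beta_1,\; q_{2i}\,x_{2i}'\beta_2;\;
  q_{1i} q_{2i}\,\rho\right), \qquad q = 2z - 1,$$
the exact likelihood of the four response patterns.  $\rho$ is searched
through $\operatorname{atanh}\rho$ so the optimisation is unconstrained;
a BFGS stage (analytic score) is followed by Newton polishing until the
score norm is below $10^{-6}$.  The reported Wald statistic for
$H_0: \rho = 0$ is $(\hat\rho / \widehat{SE}(\hat\rho))^2$ with the SE
delta-transformed back to the natural scale.  `response_correlation()`
returns the raw (phi) correlation of the two binary answers, which is a
different — and always smaller in magnitude — quantity than the latent
$\hat\rho$.

Numerical notes:

* The likelihood kernel `bivariate_cdf()` evaluates the standard
  bivariate normal CDF by single Gauss–Legendre quadrature of the
  tetrachoric integral (3/6/10 nodes by correlation strength), switching
  to an expansion about $|\rho| = 1$ with corrective quadrature when
  $|\rho| \ge 0.925$; absolute error is near machine precision, and the
  test suite certifies $10^{-10}$ against an independent adaptive
  Gauss–Kronrod oracle.  $\rho = \pm 1$ uses the exact degenerate forms.
* Likelihood contributions are clamped at $10^{-300}$ before logging.
* Perfect separation is detected as a standardized coefficient exceeding
  50 and raised as an error rather than reported as a spuriously
  converged fit; non-convergence is a warning that carries the
  gradient-norm trace.
* A fitted $|\hat\rho|$ above 0.9999 triggers a boundary warning.
* `fix_rho = 0` forces independent equations; the test suite uses the
  exact factorisation of the joint likelihood into the two univariate
  probits as an oracle identity.

## Effects coding

Categorical covariates are deviation-coded (`encode_effects()`): a
$k$-level covariate yields $k-1$ columns in $\{-1, 0, 1\}$, the reference
level carrying $-1$ everywhere, so that level effects sum to zero and the
reference effect is recoverable as minus the sum of the estimated ones
(`reference_effect()`).  By default the reference is the last level in
schema order (postgraduate education, income ≥ MYR 7001, and so on);
the choice is configurable because published tables rarely state which
level was dropped.

## Mean WTP and Krinsky–Robb intervals

With a fitted equation whose price variable has coefficient $\beta_0$,
mean WTP is the closed form
$$\widehat{\mathrm{WTP}} = -\,\bar X' \hat\beta_{-0} / \hat\beta_0,$$
where $\bar X$ holds the sample means of the non-bid columns (1 for the
constant).  `mean_wtp()` evaluates it — for the bivariate fit from
equation 2 by default, since the follow-up bid is that equation's price
variable and the conventional "double-bounded" estimate reads off that
equation; `equation = 1` gives the single-bounded analogue.

`krinsky_robb()` simulates the sampling distribution of this ratio:
parameter vectors are drawn from
$N(\hat\theta, \widehat V)$ via a symmetric eigenvalue square root
(10,000 draws by default, deterministic given `seed`), each draw is
pushed through the closed form, and a percentile interval is taken.  The
achieved significance level (ASL) is the fraction of draws with WTP at or
below zero.  Three summaries of the draw distribution are reported
separately — plug-in point, draw mean, draw median — rather than asserted
equal.  Negative-WTP draws are retained (they are what produces a
negative lower bound when the bid coefficient is weakly identified); only
draws with a numerically degenerate bid coefficient are discarded and
counted, with a warning beyond 1%.  Monte-Carlo standard errors for the
two endpoints accompany the interval so users can judge simulation noise
against doubling the draw count.

## Survey design arithmetic

`krejcie_morgan()` evaluates the finite-population sample-size formula
$$s = \frac{z^2 p (1-p)/e^2}{1 + z^2 p (1-p)/(e^2 N)},$$
rounded half-up and capped at $N$; the conventional inputs ($p = 0.5$,
$e = 0.05$, $z = 1.96$) give 384 for the Selangor parent population.
`allocate_proportional()` apportions the total across strata by the
largest-remainder (Hamilton) method with ties to the larger stratum —
chosen because independent per-stratum rounding does not sum exactly to
the total (and indeed no single rounding rule reproduces every cell of
the published allocation table; the stable cells, such as Petaling's 127,
are reproduced).  `myr_to_usd()` applies the fixed ratio $11.10/50 =
0.222$ USD/MYR with half-up rounding to 2 decimals, matching the
published currency equivalences.  Percentages throughout are rounded
half-up to 1 decimal; where a published percentage disagrees with its own
count ratio, the package reproduces the arithmetic, not the misprint.

## The synthetic generator

`generate_respondents()` draws covariates from the surveyed population's
category frequencies (70.26% female, 64.87% Malay, 40.51% bachelor's
degree, districts proportional to population), forms the latent mean
$x'\gamma$ in MYR, adds bivariate-normal noise with SD $\sigma$ and
correlation $\rho$, assigns the initial bid uniformly over the schedule,
and plays out the DBDC protocol.  Defaults — intercept-only $\gamma_0 =
400$, $\sigma = 300$, $\rho = 0.7$ — were fixed once so that simulated
pattern shares resemble the published response distribution, and double
as the truth for the recovery tests (`bid` coefficients $-1/\sigma$,
intercepts $\gamma_0/\sigma$, mean WTP $\gamma_0$).
`pattern_probabilities()` is the generator's analytic oracle: the four
orthant probabilities implied by the latent model, against which
simulated frequencies are checked.

What the generator deliberately does **not** emulate: the study's
unequal bid-group sizes (the assignment scheme was not described, so
uniform assignment is a stand-in, not a claim); the 52 excluded
never-payers (no protest-zero hurdle process); item nonresponse; and any
real dependence of WTP on covariates unless the user puts it into
`gamma`.  Tests passing on this generator therefore certify the
estimators under the model's own assumptions, not the field realism of
those assumptions.

## Problem sizes used by the test suite

Oracle-equivalence checks run on grids and an $n = 8$ instance in
seconds.  Parameter recovery uses single datasets of $n = 5000$ (joint
fit) and $n = 20000$ (mean-WTP recovery).  The replication study behind
the efficiency and coverage checks uses 300 DBDC samples at the survey's
own size $n = 390$: per replicate, the single-bounded probit and the
joint fit are estimated and the equation-2 Krinsky–Robb interval is
computed.  Under the seemingly-unrelated parameterisation the
double-bounded efficiency gain is intrinsically modest — the large gains
reported for DBDC in the valuation literature come from constraining both
answers to a single preference equation (interval-data likelihood),
which this design keeps free — so the Monte-Carlo SD comparison is close
and, at a few hundred replicates, noisier than the underlying asymptotic
ordering; robust spread measures order the two estimators more stably
than the raw SD.

## Known limitations

* Follow-up-bid anchoring or shift effects are not modelled; the second
  answer is taken at face value.
* The NN floor and the uniform bid assignment are conventions, not
  estimates.
* Krinsky–Robb percentile intervals for a coefficient ratio are not
  guaranteed to bracket the plug-in point in pathological fits; the
  object reports all quantities rather than enforcing the bracketing.
* The chi-square screen and VIF are descriptive aids; no model-selection
  automation is provided, matching the practice of reporting the screen
  and then choosing equations by hand.
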