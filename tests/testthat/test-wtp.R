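# Mean WTP and Krinsky-Robb inference.

test_that("closed-form mean WTP follows -xbar.beta / beta0", {
  expect_equal(mean_wtp(c(`(Intercept)` = 2, bid1 = -0.01),
                        xbar = c(`(Intercept)` = 1), bid_name = "bid1"),
               200)
  expect_equal(mean_wtp(c(`(Intercept)` = 0, bid1 = -0.5),
                        xbar = c(`(Intercept)` = 1), bid_name = "bid1"),
               0)
  # covariates enter through their sample means
  expect_equal(mean_wtp(c(`(Intercept)` = 1, bid1 = -0.01, x = 0.5),
                        xbar = c(`(Intercept)` = 1, x = 0.4), "bid1"),
               120)
  expect_error(mean_wtp(c(`(Intercept)` = 2, bid1 = 0),
                        c(`(Intercept)` = 1), "bid1"), "zero")
  expect_error(mean_wtp(c(a = 1), c(a = 1), "bid1"), "not found")
})

test_that("mean WTP recovers the latent intercept on synthetic data", {
  cfg <- synthetic_config(n = 5000, seed = 1001)
  d <- generate_respondents(cfg)
  f <- fit_probit(design_matrix(d, bid = "bid1"), d$z1)
  est <- mean_wtp(f, se = TRUE)
  expect_lt(abs(est - 400), 3 * attr(est, "se"))
})

test_that("a zero covariance collapses the interval onto the point", {
  cf <- c(`(Intercept)` = 2, bid1 = -0.01)
  V <- matrix(0, 2, 2, dimnames = list(names(cf), names(cf)))
  est <- krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1", seed = 5)
  expect_equal(est$ci_lower, 200)
  expect_equal(est$ci_upper, 200)
  expect_equal(est$point, 200)
  expect_true(est$asl %in% c(0, 1))
  expect_equal(est$asl, 0)   # WTP = 200 > 0 in every draw
})

test_that("the ASL is exactly the share of non-positive draws", {
  cf <- c(`(Intercept)` = 0.3, bid1 = -0.01)
  V <- diag(c(0.2, 1e-6)^2)
  dimnames(V) <- list(names(cf), names(cf))
  est <- krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1",
                      n_draws = 5000, seed = 9)
  expect_equal(est$asl, mean(est$draws <= 0))
  expect_gt(est$asl, 0)  # the intercept straddles zero at this SE
})

test_that("Krinsky-Robb matches an independent re-implementation", {
  cf <- c(`(Intercept)` = 2, bid1 = -0.01)
  V <- diag(c(0.04, 1e-6))
  dimnames(V) <- list(names(cf), names(cf))
  est <- krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1",
                      n_draws = 10000, seed = 11)
  orc <- kr_oracle(cf, V, c(`(Intercept)` = 1), "bid1",
                   n_draws = 10000, seed = 22)
  # quantile MC SE ~ 0.75 MYR at 10^4 draws; allow 4 combined SEs
  expect_lt(abs(est$ci_lower - orc$ci[1]), 4 * sqrt(2) * 0.75)
  expect_lt(abs(est$ci_upper - orc$ci[2]), 4 * sqrt(2) * 0.75)
  expect_lt(abs(est$asl - orc$asl), 0.005)
  # deterministic given the seed
  est2 <- krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1",
                       n_draws = 10000, seed = 11)
  expect_identical(est$draws, est2$draws)
})

test_that("doubling the draws moves the endpoints less than the reported MC error", {
  cf <- c(`(Intercept)` = 2, bid1 = -0.01)
  V <- diag(c(0.04, 1e-6))
  dimnames(V) <- list(names(cf), names(cf))
  e1 <- krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1",
                     n_draws = 10000, seed = 31)
  e2 <- krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1",
                     n_draws = 20000, seed = 32)
  tol <- 3 * sqrt(e1$ci_mc_se^2 + e2$ci_mc_se^2)
  expect_lt(abs(e1$ci_lower - e2$ci_lower), tol[1])
  expect_lt(abs(e1$ci_upper - e2$ci_upper), tol[2])
})

test_that("degenerate bid-coefficient draws are discarded with a warning", {
  cf <- c(`(Intercept)` = 1, bid1 = 1e-15)
  V <- matrix(0, 2, 2, dimnames = list(names(cf), names(cf)))
  expect_error(
    expect_warning(
      krinsky_robb(cf, V, c(`(Intercept)` = 1), "bid1", seed = 1),
      "degenerate bid coefficient"),
    "all draws")
})

test_that("the ASL falls as the true mean WTP rises", {
  asl <- vapply(c(0, 250, 600), function(g0) {
    d <- generate_respondents(synthetic_config(
      n = 400, gamma = c("(Intercept)" = g0), seed = 913))
    f <- fit_probit(design_matrix(d, bid = "bid1"), d$z1)
    krinsky_robb(f, seed = 914)$asl
  }, numeric(1))
  expect_true(all(diff(asl) <= 0))
  expect_gt(asl[1], asl[3])
})

test_that("fit-object methods agree with the default method", {
  d <- generate_respondents(synthetic_config(n = 800, seed = 12))
  f <- fit_probit(design_matrix(d, bid = "bid1"), d$z1)
  est_fit <- krinsky_robb(f, seed = 3)
  est_def <- krinsky_robb(coef(f), vcov(f), f$design$xbar,
                          f$design$bid_name, seed = 3)
  expect_equal(est_fit$ci_lower, est_def$ci_lower)
  expect_equal(est_fit$draws, est_def$draws)
  bf <- fit_bivariate_probit(design_matrix(d, "bid1"),
                             design_matrix(d, "bid2"), d$z1, d$z2)
  e2 <- krinsky_robb(bf, equation = 2, seed = 4)
  e1 <- krinsky_robb(bf, equation = 1, seed = 4)
  expect_equal(e2$point, mean_wtp(bf, equation = 2))
  expect_equal(e1$point, mean_wtp(bf, equation = 1))
})
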