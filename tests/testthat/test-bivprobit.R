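# Bivariate normal CDF kernel and the seemingly-unrelated bivariate probit.

test_that("bivariate CDF matches closed forms at the median orthant", {
  expect_equal(bivariate_cdf(0, 0, 0), 0.25, tolerance = 1e-14)
  for (r in c(-0.9, -0.5, 0.3, 0.6, 0.925, 0.99))
    expect_equal(bivariate_cdf(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-12)
})

test_that("bivariate CDF agrees with adaptive quadrature oracles", {
  # 1-D Gauss-Kronrod reduction of the 2-D integral
  pts <- expand.grid(a = c(-2.5, -0.3, 0.5, 1.7),
                     b = c(-1.5, 0, 0.8, 2.2),
                     rho = c(-0.99, -0.6, 0.3, 0.7, 0.95))
  for (i in seq_len(nrow(pts)))
    expect_equal(bivariate_cdf(pts$a[i], pts$b[i], pts$rho[i]),
                 bvn_quad_oracle(pts$a[i], pts$b[i], pts$rho[i]),
                 tolerance = 1e-11)
  # direct 2-D adaptive quadrature of the density at a moderate point
  # (integral2 itself only delivers ~1e-8 absolute accuracy)
  expect_lt(abs(bivariate_cdf(0.5, -0.3, 0.6) -
                  bvn_2d_oracle(0.5, -0.3, 0.6)), 1e-7)
})

test_that("degenerate correlations and infinite limits use exact forms", {
  expect_equal(bivariate_cdf(0.7, 1.2, 1), pnorm(0.7))
  expect_equal(bivariate_cdf(0.7, -1.2, -1),
               max(0, pnorm(0.7) + pnorm(-1.2) - 1))
  expect_equal(bivariate_cdf(0.4, -0.3, -1),
               pnorm(0.4) + pnorm(-0.3) - 1)
  expect_equal(bivariate_cdf(Inf, 0.3, 0.5), pnorm(0.3))
  expect_equal(bivariate_cdf(0.3, Inf, -0.2), pnorm(0.3))
  expect_equal(bivariate_cdf(-Inf, 0.3, 0.5), 0)
  expect_equal(bivariate_cdf(Inf, Inf, 0.5), 1)
  # vector recycling over mixed regimes
  v <- bivariate_cdf(c(0, 0.5, -Inf), c(0, -0.3, 1), c(0.6, 0.6, 0.6))
  expect_equal(v[1], 0.25 + asin(0.6) / (2 * pi), tolerance = 1e-12)
  expect_equal(v[3], 0)
})

test_that("raw response correlation equals the phi coefficient", {
  expect_equal(response_correlation(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
  expect_equal(response_correlation(c(0, 1, 1, 0), c(1, 0, 0, 1)), -1)
  # published pattern totals arranged as a 2x2
  z1 <- rep(c(1, 1, 0, 0), c(194, 42, 69, 85))
  z2 <- rep(c(1, 0, 1, 0), c(194, 42, 69, 85))
  phi <- (194 * 85 - 42 * 69) /
    sqrt(236 * 154 * 263 * 127)  # (ad-bc)/sqrt(margin products)
  expect_equal(response_correlation(z1, z2), phi, tolerance = 1e-12)
  expect_error(response_correlation(c(1, 1), c(0, 1)), "zero variance")
})

test_that("with rho fixed at zero the joint likelihood factorises", {
  d <- generate_respondents(synthetic_config(n = 600, seed = 55))
  ds1 <- design_matrix(d, "bid1", "education")
  ds2 <- design_matrix(d, "bid2", "education")
  f0 <- fit_bivariate_probit(ds1, ds2, d$z1, d$z2, fix_rho = 0)
  expect_lt(abs(f0$loglik - sum(f0$loglik_univariate)), 1e-8)
  # the rho-constrained fit never beats the unconstrained one
  f <- fit_bivariate_probit(ds1, ds2, d$z1, d$z2)
  expect_gte(f$loglik, f0$loglik - 1e-8)
})

test_that("per-observation pattern contributions sum to one", {
  d <- generate_respondents(synthetic_config(n = 50, seed = 4))
  ds1 <- design_matrix(d, "bid1"); ds2 <- design_matrix(d, "bid2")
  f <- fit_bivariate_probit(ds1, ds2, d$z1, d$z2)
  b1 <- f$beta1; b2 <- f$beta2; rho <- f$rho
  eta1 <- drop(ds1$X %*% b1); eta2 <- drop(ds2$X %*% b2)
  total <- rep(0, nrow(ds1$X))
  for (z1 in 0:1) for (z2 in 0:1) {
    q1 <- 2 * z1 - 1; q2 <- 2 * z2 - 1
    total <- total + bivariate_cdf(q1 * eta1, q2 * eta2, q1 * q2 * rho)
  }
  expect_lt(max(abs(total - 1)), 1e-10)
})

test_that("the joint log-likelihood matches quadrature oracles on a tiny instance", {
  # n = 8, one covariate, parameters held fixed
  X1 <- cbind(`(Intercept)` = 1, x = c(-1.5, -1, -0.5, 0, 0.25, 0.5, 1, 1.5))
  X2 <- X1
  z1 <- c(0, 0, 1, 0, 1, 1, 0, 1)
  z2 <- c(0, 1, 0, 0, 1, 0, 1, 1)
  theta <- c(0.3, -0.6, -0.2, 0.8, atanh(0.55))
  q1 <- 2 * z1 - 1; q2 <- 2 * z2 - 1
  nll <- dbdcwtp:::.bivp_parts(theta, X1, X2, q1, q2)$nll
  ll_gk <- 0   # adaptive Gauss-Kronrod reduction, ~1e-13 accurate
  ll_2d <- 0   # direct 2-D adaptive quadrature, ~1e-8 accurate
  for (i in 1:8) {
    w1 <- q1[i] * sum(X1[i, ] * theta[1:2])
    w2 <- q2[i] * sum(X2[i, ] * theta[3:4])
    r <- q1[i] * q2[i] * 0.55
    ll_gk <- ll_gk + log(bvn_quad_oracle(w1, w2, r))
    ll_2d <- ll_2d + log(bvn_2d_oracle(w1, w2, r, lo = -8, tol = 1e-12))
  }
  expect_lt(abs(-nll - ll_gk), 1e-8)
  expect_lt(abs(-nll - ll_2d), 1e-6)
})

test_that("generator parameters are recovered by the joint fit", {
  cfg <- synthetic_config(n = 1500, seed = 314)
  d <- generate_respondents(cfg)
  f <- fit_bivariate_probit(design_matrix(d, "bid1"),
                            design_matrix(d, "bid2"), d$z1, d$z2)
  expect_true(f$converged)
  expect_lt(abs(f$rho - 0.7), 3 * f$rho_se)
  se <- sqrt(diag(vcov(f)))
  expect_lt(abs(f$beta1[["bid1"]] + 1 / 300), 3 * se[["eq1:bid1"]])
  expect_lt(abs(f$beta2[["bid2"]] + 1 / 300), 3 * se[["eq2:bid2"]])
  expect_lt(f$beta1[["bid1"]], 0)
  expect_lt(f$beta2[["bid2"]], 0)
  expect_gt(f$wald_rho$statistic, qchisq(0.95, 1))
})

test_that("the Wald statistic is invariant to flipping both response codings", {
  d <- generate_respondents(synthetic_config(n = 500, seed = 81))
  ds1 <- design_matrix(d, "bid1"); ds2 <- design_matrix(d, "bid2")
  f <- fit_bivariate_probit(ds1, ds2, d$z1, d$z2)
  g <- fit_bivariate_probit(ds1, ds2, 1 - d$z1, 1 - d$z2)
  expect_equal(g$rho, f$rho, tolerance = 1e-5)
  expect_equal(g$beta1, -f$beta1, tolerance = 1e-4)
  expect_equal(g$wald_rho$statistic, f$wald_rho$statistic,
               tolerance = 1e-3)
})
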