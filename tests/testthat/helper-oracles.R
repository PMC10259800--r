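# Shared fixtures and independent oracles for the test suite.

# Published response-distribution counts: initial bid x pattern.
table3_counts <- function() {
  m <- rbind(
    `100` = c(40, 3, 12, 6),
    `150` = c(32, 6, 16, 7),
    `200` = c(32, 11, 10, 13),
    `250` = c(28, 3, 8, 17),
    `300` = c(17, 3, 12, 16),
    `350` = c(32, 8, 8, 17),
    `400` = c(13, 8, 3, 9))
  colnames(m) <- c("YY", "YN", "NY", "NN")
  m
}

# Expand a bid-by-pattern count matrix into a schema-complete respondent
# table (constant placeholder covariates).
respondents_from_counts <- function(counts, design = bid_design()) {
  rows <- list()
  for (b in rownames(counts)) {
    bid1 <- as.numeric(b)
    for (p in colnames(counts)) {
      k <- counts[b, p]
      if (k == 0) next
      z1 <- as.integer(substr(p, 1, 1) == "Y")
      z2 <- as.integer(substr(p, 2, 2) == "Y")
      rows[[paste(b, p)]] <- data.frame(
        bid1 = rep(bid1, k), z1 = z1,
        bid2 = bid1 + ifelse(z1 == 1, design$increment, -design$increment),
        z2 = z2)
    }
  }
  d <- do.call(rbind, rows)
  d <- data.frame(id = sprintf("R%05d", seq_len(nrow(d))),
                  district = "petaling", gender = "female",
                  age_band = "31-40", ethnicity = "malay",
                  education = "bachelor", income_band = ">=7001",
                  d, row.names = NULL)
  validate_respondents(d, design = design)
}

# Bivariate normal CDF by 1-D adaptive Gauss-Kronrod quadrature of the
# conditional probability (independent of the package's algorithm).
bvn_quad_oracle <- function(a, b, rho) {
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((b - rho * x) / s),
                   -Inf, a, rel.tol = 1e-13, abs.tol = 1e-13)$value
}

# Bivariate normal CDF by 2-D adaptive quadrature of the joint density.
bvn_2d_oracle <- function(a, b, rho, lo = -8, tol = 1e-11) {
  pracma::integral2(function(x, y)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2)),
    lo, a, lo, b, reltol = tol)$Q
}

# Two-parameter probit (intercept + bid) by iterative grid refinement of
# the Bernoulli log-likelihood; brute force, no gradients.
probit_grid_oracle <- function(bid, z, n_iter = 45) {
  ll <- function(a, b) {
    eta <- a + b * bid
    sum(stats::pnorm(ifelse(z == 1, eta, -eta), log.p = TRUE))
  }
  centre <- c(0, 0); width <- c(5, 0.05)
  for (it in seq_len(n_iter)) {
    as <- seq(centre[1] - width[1], centre[1] + width[1], length.out = 17)
    bs <- seq(centre[2] - width[2], centre[2] + width[2], length.out = 17)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(ll, grid$a, grid$b)
    centre <- unlist(grid[which.max(vals), ])
    width <- width * 0.35
  }
  centre
}

# Independent Krinsky-Robb re-implementation (Cholesky draws).
kr_oracle <- function(coefficients, covariance, xbar, bid_name,
                      n_draws = 10000, seed = 1, level = 0.95) {
  set.seed(seed)
  L <- chol(covariance + diag(1e-300, nrow(covariance)))
  Z <- matrix(stats::rnorm(n_draws * length(coefficients)), n_draws)
  draws <- sweep(Z %*% L, 2, coefficients, "+")
  colnames(draws) <- names(coefficients)
  wtp <- -drop(draws[, names(xbar), drop = FALSE] %*% xbar) /
    draws[, bid_name]
  alpha <- (1 - level) / 2
  list(ci = stats::quantile(wtp, c(alpha, 1 - alpha), names = FALSE),
       asl = mean(wtp <= 0), sd = stats::sd(wtp))
}
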