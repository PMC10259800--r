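# Mean WTP and Krinsky-Robb simulated confidence intervals.

#' Closed-form mean willingness to pay
#'
#' From a fitted binary-choice valuation model with a bid (price) variable,
#' mean WTP is `-(xbar . beta_nonbid) / beta0`, where `xbar` is the row
#' vector of sample means of the non-bid design columns (1 for the
#' constant) and `beta0` the bid coefficient.  For an intercept-only model
#' this is `-alpha / beta0`.
#'
#' @param object named coefficient vector, or a fitted [fit_probit()] /
#'   [fit_bivariate_probit()] object.
#' @param ... passed to methods.
#' @return mean WTP in MYR (numeric scalar; for fit methods, with an `se`
#'   attribute when `se = TRUE`).
#' @export
mean_wtp <- function(object, ...) UseMethod("mean_wtp")

#' @rdname mean_wtp
#' @param xbar named vector of non-bid column means, including 1 for the
#'   intercept.
#' @param bid_name name of the bid coefficient in `object`.
#' @export
mean_wtp.default <- function(object, xbar, bid_name, ...) {
  coefficients <- object
  stopf(!is.null(names(coefficients)), "coefficients must be named")
  stopf(bid_name %in% names(coefficients),
        "bid coefficient '%s' not found", bid_name)
  stopf(all(names(xbar) %in% names(coefficients)),
        "xbar names missing from coefficients: %s",
        paste(setdiff(names(xbar), names(coefficients)), collapse = ", "))
  beta0 <- coefficients[[bid_name]]
  stopf(beta0 != 0, "bid coefficient is zero; mean WTP undefined")
  -sum(xbar * coefficients[names(xbar)]) / beta0
}

# delta-method SE of -(xbar.b)/b0 over columns (names(xbar), bid)
.wtp_delta_se <- function(coefficients, V, xbar, bid_name) {
  beta0 <- coefficients[[bid_name]]
  wtp <- -sum(xbar * coefficients[names(xbar)]) / beta0
  grad <- c(-xbar / beta0, -wtp / beta0)
  names(grad) <- c(names(xbar), bid_name)
  idx <- names(grad)
  sqrt(drop(t(grad) %*% V[idx, idx] %*% grad))
}

#' @rdname mean_wtp
#' @param se also compute a delta-method standard error?
#' @param robust use the robust covariance for the SE?
#' @export
mean_wtp.dbdc_probit <- function(object, se = FALSE, robust = FALSE, ...) {
  d <- object$design
  stopf(!is.null(d) && !is.null(d$bid_name),
        "fit carries no design with a bid variable; use the default method")
  est <- mean_wtp(object$coefficients, d$xbar, d$bid_name)
  if (se) attr(est, "se") <- .wtp_delta_se(
    object$coefficients, vcov(object, if (robust) "robust" else "classical"),
    d$xbar, d$bid_name)
  est
}

#' @rdname mean_wtp
#' @param equation which equation of the bivariate fit to evaluate: 2
#'   (default, the double-bounded follow-up equation) or 1 (single-bounded).
#' @export
mean_wtp.dbdc_bivprobit <- function(object, equation = 2, se = FALSE,
                                    robust = TRUE, ...) {
  stopf(equation %in% 1:2, "equation must be 1 or 2")
  d <- if (equation == 1) object$design1 else object$design2
  stopf(!is.null(d) && !is.null(d$bid_name),
        "equation %d carries no design with a bid variable", equation)
  pre <- paste0("eq", equation, ":")
  xbar <- d$xbar
  names(xbar) <- paste0(pre, names(xbar))
  bid <- paste0(pre, d$bid_name)
  est <- mean_wtp(object$coefficients, xbar, bid)
  if (se) attr(est, "se") <- .wtp_delta_se(
    object$coefficients, vcov(object, if (robust) "robust" else "classical"),
    xbar, bid)
  est
}

# symmetric square root of a PSD matrix, with a diagonal jitter retry
.sym_sqrt <- function(V) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-8 * max(abs(lam), 1)) {
    V <- V + diag(abs(min(lam)) + 1e-12, nrow(V))
    ev <- eigen(V, symmetric = TRUE)
    lam <- ev$values
    stopf(min(lam) >= -1e-8 * max(abs(lam), 1),
          "covariance matrix is not positive semi-definite")
  }
  ev$vectors %*% (sqrt(pmax(lam, 0)) * t(ev$vectors))
}

#' Krinsky-Robb simulated confidence interval for mean WTP
#'
#' Parametric bootstrap of the WTP statistic: parameter vectors are drawn
#' from the multivariate normal with mean at the estimates and the estimated
#' covariance (via a symmetric matrix square root), each draw is propagated
#' through the closed-form mean-WTP expression, and a percentile interval is
#' taken.  The achieved significance level (ASL) for testing `H0: WTP <= 0`
#' against `H1: WTP > 0` is the fraction of draws with WTP at or below
#' zero.  Draws whose bid coefficient is numerically degenerate are
#' discarded (with a warning if they exceed 1% of the total).  Negative-WTP
#' draws are retained: percentile intervals from a coefficient ratio can be
#' strongly asymmetric and may extend below zero.
#'
#' @param object named coefficient vector, or a fitted [fit_probit()] /
#'   [fit_bivariate_probit()] object.
#' @param ... passed to methods.
#' @return An object of class `wtp_estimate`: list with `point` (plug-in
#'   estimate), `draw_mean`, `draw_median`, `ci_lower`, `ci_upper`,
#'   `ci_mc_se` (Monte-Carlo SEs of the two endpoints), `level`, `asl`,
#'   `n_draws`, `n_used`, `n_discarded`, `seed`, `bid_name` and the vector
#'   of simulated WTP values (`draws`).
#' @export
krinsky_robb <- function(object, ...) UseMethod("krinsky_robb")

#' @rdname krinsky_robb
#' @param covariance estimated covariance matrix of the coefficients (rows
#'   and columns named like them).
#' @inheritParams mean_wtp.default
#' @param n_draws number of parameter draws (default 10000).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param level confidence level for the percentile interval.
#' @param tol relative tolerance below which a drawn bid coefficient counts
#'   as degenerate.
#' @export
krinsky_robb.default <- function(object, covariance, xbar, bid_name,
                                 n_draws = 10000L, seed = NULL,
                                 level = 0.95, tol = 1e-12, ...) {
  coefficients <- object
  point <- mean_wtp(coefficients, xbar, bid_name)  # validates inputs
  p <- length(coefficients)
  stopf(is.matrix(covariance) && all(dim(covariance) == p),
        "covariance must be %d x %d", p, p)
  stopf(!is.null(dimnames(covariance)) &&
          identical(rownames(covariance), names(coefficients)),
        "covariance dimnames must match coefficient names")
  stopf(is_number(level) && level > 0 && level < 1,
        "level must be in (0, 1)")
  S <- .sym_sqrt(covariance)
  draws <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
    sweep(Z %*% S, 2, coefficients, "+")
  })
  colnames(draws) <- names(coefficients)
  b0 <- draws[, bid_name]
  degenerate <- abs(b0) < tol * max(1, abs(coefficients[[bid_name]]))
  if (mean(degenerate) > 0.01)
    warning(sprintf("%.1f%% of draws had a degenerate bid coefficient",
                    100 * mean(degenerate)))
  keep <- !degenerate
  stopf(sum(keep) >= 2,
        "all draws of the bid coefficient are numerically degenerate")
  wtp_d <- -drop(draws[keep, names(xbar), drop = FALSE] %*% xbar) / b0[keep]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(wtp_d, c(alpha, 1 - alpha), names = FALSE)
  # MC SE of a sample quantile: sqrt(p(1-p)/n) / f_hat(q)
  dens <- stats::density(wtp_d, n = 1024)
  f_at <- stats::approx(dens$x, dens$y, xout = ci, rule = 2)$y
  ci_mc_se <- sqrt(c(alpha, alpha) * (1 - alpha) / length(wtp_d)) /
    pmax(f_at, .Machine$double.eps)
  structure(list(point = point,
                 draw_mean = mean(wtp_d),
                 draw_median = stats::median(wtp_d),
                 ci_lower = ci[1], ci_upper = ci[2], ci_mc_se = ci_mc_se,
                 level = level, asl = mean(wtp_d <= 0),
                 n_draws = as.integer(n_draws),
                 n_used = length(wtp_d),
                 n_discarded = as.integer(sum(degenerate)),
                 seed = seed, bid_name = bid_name, draws = wtp_d),
            class = "wtp_estimate")
}

#' @rdname krinsky_robb
#' @param robust draw from the robust (sandwich) covariance?
#' @export
krinsky_robb.dbdc_probit <- function(object, robust = FALSE, ...) {
  d <- object$design
  stopf(!is.null(d) && !is.null(d$bid_name),
        "fit carries no design with a bid variable; use the default method")
  krinsky_robb(object$coefficients,
               vcov(object, if (robust) "robust" else "classical"),
               d$xbar, d$bid_name, ...)
}

#' @rdname krinsky_robb
#' @param equation which equation's WTP to simulate (2 = double-bounded,
#'   default; 1 = single-bounded).  Draws are taken from the full joint
#'   covariance so cross-equation uncertainty is propagated.
#' @export
krinsky_robb.dbdc_bivprobit <- function(object, equation = 2,
                                        robust = TRUE, ...) {
  stopf(equation %in% 1:2, "equation must be 1 or 2")
  d <- if (equation == 1) object$design1 else object$design2
  stopf(!is.null(d) && !is.null(d$bid_name),
        "equation %d carries no design with a bid variable", equation)
  pre <- paste0("eq", equation, ":")
  xbar <- d$xbar
  names(xbar) <- paste0(pre, names(xbar))
  krinsky_robb(object$coefficients,
               vcov(object, if (robust) "robust" else "classical"),
               xbar, paste0(pre, d$bid_name), ...)
}

#' @export
print.wtp_estimate <- function(x, rate = 11.10 / 50, ...) {
  cat("Krinsky-Robb WTP estimate\n")
  cat(sprintf("  plug-in mean WTP: MYR %.2f (USD %.2f)\n",
              x$point, myr_to_usd(max(x$point, 0), rate)))
  cat(sprintf("  draws: mean %.2f, median %.2f (%d used, %d discarded)\n",
              x$draw_mean, x$draw_median, x$n_used, x$n_discarded))
  cat(sprintf("  %d%% CI: [%.2f, %.2f]\n", round(100 * x$level),
              x$ci_lower, x$ci_upper))
  cat(sprintf("  ASL (H0: WTP <= 0): %.3f\n", x$asl))
  invisible(x)
}
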