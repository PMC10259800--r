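# Univariate probit maximum likelihood (single-bounded analysis).

# log Phi(q*eta) and the inverse-Mills-type weight, numerically safe in the
# tails via log-scale evaluation.
.probit_lam <- function(eta, q) {
  q * exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(q * eta, log.p = TRUE))
}

# least squares on the latent-scale transform 1.6449*(2z-1) as a starting
# value; the probit log-likelihood is globally concave so this only speeds
# up convergence.
.probit_start <- function(X, q) {
  b <- tryCatch(qr.coef(qr(X), 1.6449 * q), error = function(e) NULL)
  if (is.null(b) || any(!is.finite(b))) b <- rep(0, ncol(X))
  b
}

#' Univariate probit by maximum likelihood
#'
#' Fits `P(z = 1 | x) = Phi(x' beta)` by Newton-Raphson with step-halving,
#' converging to gradient norm below `tol` (default 1e-8).  Both the
#' classical (inverse observed information) and the robust sandwich
#' covariance `A^-1 B A^-1` (A = observed information, B = summed outer
#' products of per-observation scores) are returned.  Used on the first
#' DBDC response this is the single-bounded valuation model; the negative
#' of the bid coefficient's reciprocal scales the latent WTP.
#'
#' @param design a [design_matrix()] or a numeric model matrix whose first
#'   columns include an intercept.
#' @param response binary 0/1 vector of length `nrow`.
#' @param tol convergence tolerance on the maximum absolute score.
#' @param max_iter Newton iteration cap.
#' @return An object of class `dbdc_probit` with elements `coefficients`,
#'   `vcov` (classical), `vcov_robust`, `loglik`, `loglik_null`,
#'   `converged`, `iterations`, `trace` (gradient norms), `n`, `design`.
#' @export
#' @examples
#' cfg <- synthetic_config(n = 500, seed = 7)
#' d <- generate_respondents(cfg)
#' fit <- fit_probit(design_matrix(d, bid = "bid1"), d$z1)
#' coef(fit)
fit_probit <- function(design, response, tol = 1e-8, max_iter = 50L) {
  X <- .as_model_matrix(design)
  z <- as.numeric(response)
  stopf(all(z %in% c(0, 1)), "response must be binary 0/1")
  stopf(nrow(X) == length(z), "design and response lengths differ")
  stopf(nrow(X) > ncol(X), "more parameters than observations")
  sds <- apply(X, 2, stats::sd)
  const_cols <- names(which(sds == 0))
  stopf(identical(const_cols, character(0)) ||
          identical(const_cols, "(Intercept)"),
        "constant non-intercept column(s): %s",
        paste(setdiff(const_cols, "(Intercept)"), collapse = ", "))

  q <- 2 * z - 1
  b <- .probit_start(X, q)
  loglik <- function(b) sum(stats::pnorm(q * drop(X %*% b), log.p = TRUE))
  ll <- loglik(b)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    lam <- .probit_lam(eta, q)
    grad <- drop(crossprod(X, lam))
    trace <- c(trace, max(abs(grad)))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- lam * (lam + eta)           # > 0: loglik is globally concave
    H <- crossprod(X, w * X)
    step <- drop(solve(H, grad))
    # step-halving
    for (h in 0:30) {
      b_new <- b + step / 2^h
      ll_new <- loglik(b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    b <- b_new
    ll <- ll_new
  }
  if (!converged) {
    eta <- drop(X %*% b)
    lam <- .probit_lam(eta, q)
    grad <- drop(crossprod(X, lam))
    if (max(abs(grad)) < tol) converged <- TRUE
    else warning(sprintf(
      "probit did not converge in %d iterations; gradient-norm trace: %s",
      max_iter, paste(signif(trace, 3), collapse = " ")))
  }

  # perfect separation pushes standardized coefficients without bound
  std <- abs(b) * ifelse(sds > 0, sds, 1)
  std["(Intercept)" == colnames(X)] <- 0
  stopf(all(std < 50),
        "perfect separation suspected (diverging coefficient in: %s)",
        paste(colnames(X)[std >= 50], collapse = ", "))

  eta <- drop(X %*% b)
  lam <- .probit_lam(eta, q)
  w <- lam * (lam + eta)
  A <- crossprod(X, w * X)               # observed information
  V <- solve(A)
  B <- crossprod(lam * X)                # sum of score outer products
  V_rob <- V %*% B %*% V
  names(b) <- colnames(X)
  dimnames(V) <- dimnames(V_rob) <- list(colnames(X), colnames(X))

  p1 <- mean(z)
  ll_null <- if (p1 %in% c(0, 1)) 0 else
    length(z) * (p1 * log(p1) + (1 - p1) * log(1 - p1))

  structure(list(coefficients = b, vcov = V, vcov_robust = V_rob,
                 loglik = loglik(b), loglik_null = ll_null,
                 converged = converged, iterations = length(trace),
                 trace = trace, n = length(z),
                 design = if (inherits(design, "dbdc_design")) design
                          else NULL),
            class = "dbdc_probit")
}

#' @export
coef.dbdc_probit <- function(object, ...) object$coefficients

#' @export
logLik.dbdc_probit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @param type `"classical"` (inverse information) or `"robust"`
#'   (sandwich).
#' @rdname fit_probit
#' @param object,x a fitted `dbdc_probit`.
#' @param ... unused.
#' @export
vcov.dbdc_probit <- function(object, type = c("classical", "robust"), ...) {
  switch(match.arg(type), classical = object$vcov,
         robust = object$vcov_robust)
}

# z / p coefficient table used by both probit summaries
.coef_table <- function(b, V) {
  se <- sqrt(diag(V))
  zval <- b / se
  cbind(Estimate = b, `Std. Error` = se, `z value` = zval,
        `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
}

#' @rdname fit_probit
#' @export
summary.dbdc_probit <- function(object,
                                type = c("classical", "robust"), ...) {
  type <- match.arg(type)
  out <- list(table = .coef_table(object$coefficients,
                                  vcov(object, type)),
              type = type, loglik = object$loglik, n = object$n,
              converged = object$converged)
  class(out) <- "summary.dbdc_probit"
  out
}

#' @export
print.summary.dbdc_probit <- function(x, digits = 4, ...) {
  cat(sprintf("Probit ML (n = %d, logLik = %.3f, %s SEs)\n",
              x$n, x$loglik, x$type))
  stats::printCoefmat(x$table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
print.dbdc_probit <- function(x, ...) {
  cat(sprintf("Probit ML fit: n = %d, logLik = %.3f, converged = %s\n",
              x$n, x$loglik, x$converged))
  print(x$coefficients)
  invisible(x)
}
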