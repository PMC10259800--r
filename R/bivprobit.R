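# Seemingly-unrelated bivariate probit and its bivariate-normal CDF kernel.

# Gauss-Legendre weights/abscissae (half rules; nodes are symmetric) for the
# single-quadrature bivariate normal algorithm of Genz (1994/2004 lineage).
.gl_w <- list(
  c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
  c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
    0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
  c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
    0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
    0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
    0.1527533871307259))
.gl_x <- list(
  c(-0.9324695142031522, -0.6612093864662647, -0.2386191860831970),
  c(-0.9815606342467191, -0.9041172563704750, -0.7699026741943050,
    -0.5873179542866171, -0.3678314989981802, -0.1252334085114692),
  c(-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
    -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
    -0.5108670019508271, -0.3737060887154196, -0.2277858511416451,
    -0.07652652113349733))

# Upper-orthant probability P(X > dh, Y > dk) for standard bivariate normal
# with correlation r (scalar); dh, dk vectors.  Absolute error ~1e-15.
.bvnd <- function(dh, dk, r) {
  ng <- if (abs(r) < 0.3) 1L else if (abs(r) < 0.75) 2L else 3L
  w <- rep(.gl_w[[ng]], 2)
  xn <- c(.gl_x[[ng]], -.gl_x[[ng]])
  h <- dh; k <- dk
  if (abs(r) < 0.925) {
    bvn <- numeric(length(h))
    if (abs(r) > 0) {
      hk <- h * k
      hs <- (h * h + k * k) / 2
      asr <- asin(r)
      sn <- sin(asr * (xn + 1) / 2)
      # M[i, j] = exp((hk_i * sn_j - hs_i) / (1 - sn_j^2))
      M <- exp(sweep(outer(hk, sn) - hs, 2, 1 - sn^2, "/"))
      bvn <- drop(M %*% w) * asr / (4 * pi)
    }
    return(bvn + stats::pnorm(-h) * stats::pnorm(-k))
  }
  # strong correlation: expansion about |r| = 1 plus corrective quadrature
  if (r < 0) k <- -k
  hk <- h * k
  bvn <- numeric(length(h))
  if (abs(r) < 1) {
    as_ <- (1 - r) * (1 + r)
    a <- sqrt(as_)
    bs <- (h - k)^2
    cc <- (4 - hk) / 8
    dd <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    ok <- asr > -100
    bvn[ok] <- (a * exp(asr) *
      (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 + cc * dd * as_^2 / 5))[ok]
    ok <- -hk < 100
    if (any(ok)) {
      b_ <- sqrt(bs)
      bvn[ok] <- bvn[ok] - (exp(-hk / 2) * sqrt(2 * pi) *
        stats::pnorm(-b_ / a) * b_ * (1 - cc * bs * (1 - dd * bs / 5) / 3))[ok]
    }
    a2 <- a / 2
    for (j in seq_along(xn)) {
      xs <- (a2 * (xn[j] + 1))^2
      rs <- sqrt(1 - xs)
      asr <- -(bs / xs + hk) / 2
      ok <- asr > -100
      if (any(ok)) {
        bvn[ok] <- bvn[ok] + (a2 * w[j] * exp(asr) *
          (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
             (1 + cc * xs * (1 + dd * xs))))[ok]
      }
    }
    bvn <- -bvn / (2 * pi)
  }
  if (r > 0) bvn + stats::pnorm(-pmax(h, k))
  else {
    bvn <- -bvn
    bvn + ifelse(k > h, stats::pnorm(k) - stats::pnorm(h), 0)
  }
}

#' Standard bivariate normal CDF
#'
#' `P(U <= a, V <= b)` for a standard bivariate normal pair with correlation
#' `rho`, to near machine precision (absolute error well below 1e-10), via a
#' single Gauss-Legendre quadrature of the tetrachoric integral with a
#' separate expansion for strong correlation.  Degenerate `rho = +/-1` uses
#' the closed forms `Phi(min(a, b))` and `max(0, Phi(a) + Phi(b) - 1)`.
#'
#' @param a,b upper limits (vectors recycle; infinite limits allowed).
#' @param rho correlation(s) in \[-1, 1\].
#' @return vector of probabilities.
#' @export
#' @examples
#' bivariate_cdf(0, 0, 0.5)           # 1/4 + asin(0.5)/(2*pi)
bivariate_cdf <- function(a, b, rho) {
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  rho <- rep_len(as.numeric(rho), n)
  stopf(all(abs(rho) <= 1, na.rm = TRUE), "|rho| must be <= 1")
  out <- rep(NA_real_, n)
  na <- is.na(a) | is.na(b) | is.na(rho)
  # degenerate correlation
  hi <- !na & rho >= 1 - 1e-12
  out[hi] <- stats::pnorm(pmin(a[hi], b[hi]))
  lo <- !na & rho <= -1 + 1e-12
  out[lo] <- pmax(0, stats::pnorm(a[lo]) + stats::pnorm(b[lo]) - 1)
  # infinite limits
  rest <- !na & !hi & !lo
  inf <- rest & (a == -Inf | b == -Inf)
  out[inf] <- 0
  one_inf <- rest & !inf & a == Inf
  out[one_inf] <- stats::pnorm(b[one_inf])
  two_inf <- rest & !inf & a < Inf & b == Inf
  out[two_inf] <- stats::pnorm(a[two_inf])
  todo <- rest & !inf & !one_inf & !two_inf
  for (r in unique(rho[todo])) {
    i <- todo & rho == r
    out[i] <- .bvnd(-a[i], -b[i], r)
  }
  pmin(pmax(out, 0), 1)
}

# standard bivariate normal density at (x, y; r)
.dbvn <- function(x, y, r) {
  s2 <- 1 - r^2
  exp(-(x^2 - 2 * r * x * y + y^2) / (2 * s2)) / (2 * pi * sqrt(s2))
}

#' Pearson correlation between the two binary responses
#'
#' The raw inter-response (phi) correlation of the first and second yes/no
#' answers — a different quantity from the latent error correlation `rho`
#' estimated by [fit_bivariate_probit()].
#'
#' @param z1,z2 equal-length binary vectors.
#' @return correlation coefficient.
#' @export
response_correlation <- function(z1, z2) {
  stopf(length(z1) == length(z2), "z1 and z2 lengths differ")
  stopf(stats::sd(z1) > 0 && stats::sd(z2) > 0,
        "zero variance in a response vector")
  stats::cor(z1, z2)
}

# negative log-likelihood machinery shared by fit and oracle checks.
# theta = (beta1, beta2[, atanh rho]); returns list(nll, scores) on demand.
.bivp_parts <- function(theta, X1, X2, q1, q2, fix_rho = NULL,
                        scores = FALSE) {
  p1 <- ncol(X1); p2 <- ncol(X2)
  b1 <- theta[seq_len(p1)]
  b2 <- theta[p1 + seq_len(p2)]
  rho <- if (is.null(fix_rho)) tanh(theta[p1 + p2 + 1]) else fix_rho
  w1 <- q1 * drop(X1 %*% b1)
  w2 <- q2 * drop(X2 %*% b2)
  rst <- q1 * q2 * rho
  P <- pmax(bivariate_cdf(w1, w2, rst), 1e-300)
  out <- list(nll = -sum(log(P)), rho = rho)
  if (scores) {
    s <- sqrt(max(1 - rho^2, 1e-300))
    g1 <- stats::dnorm(w1) * stats::pnorm((w2 - rst * w1) / s)
    g2 <- stats::dnorm(w2) * stats::pnorm((w1 - rst * w2) / s)
    S <- cbind(X1 * (q1 * g1 / P), X2 * (q2 * g2 / P))
    if (is.null(fix_rho)) {
      dr <- q1 * q2 * .dbvn(w1, w2, rst) / P * (1 - rho^2)
      S <- cbind(S, dr)
    }
    out$scores <- S
  }
  out
}

# central-difference Jacobian of the analytic gradient = Hessian of nll
.bivp_hessian <- function(theta, X1, X2, q1, q2, fix_rho, h = 1e-5) {
  p <- length(theta)
  grad_at <- function(th) -colSums(
    .bivp_parts(th, X1, X2, q1, q2, fix_rho, scores = TRUE)$scores)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h * max(1, abs(theta[j]))
    H[, j] <- (grad_at(theta + e) - grad_at(theta - e)) / (2 * e[j])
  }
  (H + t(H)) / 2
}

#' Seemingly-unrelated bivariate probit
#'
#' Joint maximum likelihood for the two DBDC responses: two probit index
#' equations (first response on the start bid, second on the follow-up bid,
#' each with its own covariates) whose latent errors are bivariate normal
#' with correlation `rho`.  The log-likelihood is
#' `sum log Phi2(q1 x1'b1, q2 x2'b2; q1 q2 rho)` with `q = 2z - 1`.  `rho`
#' is searched through its inverse hyperbolic tangent so the optimisation is
#' unconstrained; estimates are reported on the natural scale.  A robust
#' sandwich covariance and the Wald test of `rho = 0` (delta method on the
#' untransformed scale) are included.
#'
#' @param design1,design2 designs for the two equations ([design_matrix()]
#'   or plain matrices) sharing row order.
#' @param z1,z2 binary responses to the initial and follow-up bids.
#' @param fix_rho optional fixed value for `rho` (e.g. 0 to force
#'   independent equations); if given, `rho` is not estimated.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton polishing iteration cap after the quasi-Newton
#'   stage.
#' @return An object of class `dbdc_bivprobit` with elements `beta1`,
#'   `beta2`, `rho`, `coefficients` (stacked, `eq1:`/`eq2:` prefixes and
#'   `atanh(rho)`), `vcov`/`vcov_robust` (joint, on the stacked scale),
#'   `rho_se`, `wald_rho` (statistic, df, p.value), `loglik`, `converged`,
#'   `n`, `design1`, `design2`.
#' @export
#' @examples
#' cfg <- synthetic_config(n = 400, seed = 11)
#' d <- generate_respondents(cfg)
#' fit <- fit_bivariate_probit(design_matrix(d, bid = "bid1"),
#'                             design_matrix(d, bid = "bid2"),
#'                             d$z1, d$z2)
#' fit$rho
fit_bivariate_probit <- function(design1, design2, z1, z2, fix_rho = NULL,
                                 tol = 1e-6, max_iter = 50L) {
  X1 <- .as_model_matrix(design1)
  X2 <- .as_model_matrix(design2)
  z1 <- as.numeric(z1); z2 <- as.numeric(z2)
  stopf(all(c(z1, z2) %in% c(0, 1)), "responses must be binary 0/1")
  stopf(nrow(X1) == nrow(X2) && nrow(X1) == length(z1) &&
          length(z1) == length(z2), "row counts differ across inputs")
  p1 <- ncol(X1); p2 <- ncol(X2)
  n <- length(z1)
  free_rho <- is.null(fix_rho)
  stopf(n > p1 + p2 + as.integer(free_rho),
        "more parameters than observations")
  q1 <- 2 * z1 - 1; q2 <- 2 * z2 - 1

  # start from the univariate fits, atanh(rho) = 0
  f1 <- fit_probit(X1, z1)
  f2 <- fit_probit(X2, z2)
  theta <- c(f1$coefficients, f2$coefficients, if (free_rho) 0)

  fn <- function(th) .bivp_parts(th, X1, X2, q1, q2, fix_rho)$nll
  gr <- function(th) -colSums(
    .bivp_parts(th, X1, X2, q1, q2, fix_rho, scores = TRUE)$scores)
  opt <- stats::optim(theta, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  # Newton polish to drive the score norm below tol
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gr(theta)
    trace <- c(trace, max(abs(g)))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- .bivp_hessian(theta, X1, X2, q1, q2, fix_rho)
    step <- tryCatch(drop(solve(H, -g)), error = function(e) -g * 1e-3)
    nll0 <- fn(theta)
    for (hh in 0:30) {
      cand <- theta + step / 2^hh
      if (is.finite(fn(cand)) && fn(cand) <= nll0 + 1e-10) break
    }
    theta <- cand
  }
  if (!converged && max(abs(gr(theta))) < tol) converged <- TRUE
  if (!converged)
    warning(sprintf(
      "bivariate probit did not converge; gradient-norm trace: %s",
      paste(signif(trace, 3), collapse = " ")))

  parts <- .bivp_parts(theta, X1, X2, q1, q2, fix_rho, scores = TRUE)
  rho <- parts$rho
  if (abs(rho) > 0.9999)
    warning("rho estimate at the boundary (|rho| ~ 1)")

  # separation check per equation on standardized coefficients
  for (eq in 1:2) {
    X <- if (eq == 1) X1 else X2
    b <- if (eq == 1) theta[seq_len(p1)] else theta[p1 + seq_len(p2)]
    sds <- apply(X, 2, stats::sd)
    std <- abs(b) * ifelse(sds > 0, sds, 0)
    stopf(all(std < 50),
          "perfect separation suspected in equation %d (%s)", eq,
          paste(colnames(X)[std >= 50], collapse = ", "))
  }

  H <- .bivp_hessian(theta, X1, X2, q1, q2, fix_rho)
  V <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix; using pseudo-inverse")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  })
  B <- crossprod(parts$scores)
  V_rob <- V %*% B %*% V

  nm <- c(paste0("eq1:", colnames(X1)), paste0("eq2:", colnames(X2)),
          if (free_rho) "atanh(rho)")
  names(theta) <- nm
  dimnames(V) <- dimnames(V_rob) <- list(nm, nm)

  wald <- NULL
  rho_se <- NA_real_
  if (free_rho) {
    k <- p1 + p2 + 1
    rho_se <- sqrt(V_rob[k, k]) * (1 - rho^2)  # delta method, natural scale
    stat <- (rho / rho_se)^2
    wald <- list(statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
  }

  b1 <- theta[seq_len(p1)]; names(b1) <- colnames(X1)
  b2 <- theta[p1 + seq_len(p2)]; names(b2) <- colnames(X2)
  structure(list(beta1 = b1, beta2 = b2, rho = rho, rho_se = rho_se,
                 coefficients = theta, vcov = V, vcov_robust = V_rob,
                 wald_rho = wald, loglik = -parts$nll,
                 loglik_univariate = c(f1$loglik, f2$loglik),
                 converged = converged, trace = trace, n = n,
                 fixed_rho = fix_rho,
                 design1 = if (inherits(design1, "dbdc_design")) design1,
                 design2 = if (inherits(design2, "dbdc_design")) design2),
            class = "dbdc_bivprobit")
}

#' @export
coef.dbdc_bivprobit <- function(object, ...) object$coefficients

#' @export
logLik.dbdc_bivprobit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @rdname fit_bivariate_probit
#' @param object,x a fitted `dbdc_bivprobit`.
#' @param type `"robust"` (default, sandwich) or `"classical"`.
#' @param ... unused.
#' @export
vcov.dbdc_bivprobit <- function(object,
                                type = c("robust", "classical"), ...) {
  switch(match.arg(type), robust = object$vcov_robust,
         classical = object$vcov)
}

#' @rdname fit_bivariate_probit
#' @export
summary.dbdc_bivprobit <- function(object,
                                   type = c("robust", "classical"), ...) {
  type <- match.arg(type)
  V <- vcov(object, type)
  out <- list(table = .coef_table(object$coefficients, V),
              rho = object$rho, rho_se = object$rho_se,
              wald_rho = object$wald_rho, type = type,
              loglik = object$loglik, n = object$n,
              converged = object$converged)
  class(out) <- "summary.dbdc_bivprobit"
  out
}

#' @export
print.summary.dbdc_bivprobit <- function(x, digits = 4, ...) {
  cat(sprintf("Seemingly-unrelated bivariate probit (n = %d, logLik = %.3f, %s SEs)\n",
              x$n, x$loglik, x$type))
  stats::printCoefmat(x$table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("rho = %.3f (SE %.3f)\n", x$rho, x$rho_se))
  if (!is.null(x$wald_rho))
    cat(sprintf("Wald test rho = 0: Chi2(1) = %.2f, p = %.4g\n",
                x$wald_rho$statistic, x$wald_rho$p.value))
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
print.dbdc_bivprobit <- function(x, ...) {
  cat(sprintf("Bivariate probit fit: n = %d, logLik = %.3f, rho = %.3f\n",
              x$n, x$loglik, x$rho))
  cat("Equation 1:\n"); print(x$beta1)
  cat("Equation 2:\n"); print(x$beta2)
  invisible(x)
}
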