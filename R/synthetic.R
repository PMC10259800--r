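# Synthetic DBDC respondent generator with correlated latent WTP.

#' Default covariate category frequencies
#'
#' Per-covariate sampling probabilities for the synthetic generator,
#' matching the socio-economic profile of the surveyed parent population
#' (e.g. 70.26% female respondents, 64.87% Malay, 40.51% bachelor's degree)
#' and district shares proportional to population.
#'
#' @return named list; each element is a probability vector named by
#'   category level and summing to 1.
#' @export
dbdc_covariate_freqs <- function() {
  lv <- dbdc_levels()
  f <- list(
    district = c(126.1, 251.2, 1025.1, 270.1, 2157, 256.9, 1370.2, 815.2,
                 237.6) / 6509.4,
    gender = c(116, 274) / 390,
    age_band = c(29, 281, 73, 7) / 390,
    ethnicity = c(253, 93, 41, 3) / 390,
    education = c(83, 121, 158, 28) / 390,
    # the middle-low band count is reconstructed from its printed share
    # (27.69% of 390 = 108); the published count column sums to 388
    income_band = c(13, 108, 101, 41, 127) / 390
  )
  for (v in names(f)) names(f[[v]]) <- lv[[v]]
  f
}

#' Configuration for the synthetic respondent generator
#'
#' Defines the true data-generating process: latent willingness to pay
#' `WTP_k = x * gamma + eps_k` for the two valuation questions, with
#' `(eps_1, eps_2)` bivariate normal, common standard deviation `sigma` and
#' correlation `rho`.  The respondent answers yes to question k iff the
#' latent WTP is at least the bid shown.
#'
#' @param n number of respondents.
#' @param gamma named coefficient vector of the latent mean in MYR over
#'   `"(Intercept)"` and effects-coded columns `"covariate=level"` (the
#'   reference level is the last level in [dbdc_levels()] order).  Default:
#'   intercept-only with mean WTP MYR 400.
#' @param sigma latent error standard deviation (MYR), > 0.  Default 300.
#' @param rho latent error correlation across the two questions, in
#'   \[-1, 1\].  Default 0.7.
#' @param bid_design a [bid_design()].
#' @param covariate_freqs category frequencies, as
#'   [dbdc_covariate_freqs()].
#' @param seed integer seed making generation reproducible, or `NULL`.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n = 390,
                             gamma = c("(Intercept)" = 400),
                             sigma = 300,
                             rho = 0.7,
                             bid_design = dbdcwtp::bid_design(),
                             covariate_freqs = dbdc_covariate_freqs(),
                             seed = NULL) {
  stopf(is_number(n) && n >= 1 && n == round(n), "n must be a positive count")
  stopf(is_number(sigma) && sigma > 0, "sigma must be > 0")
  stopf(is_number(rho) && abs(rho) <= 1, "|rho| must be <= 1")
  stopifnot(inherits(bid_design, "bid_design"))
  stopf(!is.null(names(gamma)) && all(nzchar(names(gamma))),
        "gamma must be a named vector")
  for (v in names(covariate_freqs)) {
    p <- covariate_freqs[[v]]
    stopf(abs(sum(p) - 1) < 1e-8, "frequencies for '%s' must sum to 1", v)
    stopf(all(p >= 0), "negative frequency for '%s'", v)
  }
  cfg <- structure(list(n = as.integer(n), gamma = gamma, sigma = sigma,
                        rho = rho, bid_design = bid_design,
                        covariate_freqs = covariate_freqs,
                        seed = if (is.null(seed)) NULL else as.integer(seed)),
                   class = "synthetic_config")
  .check_gamma(cfg)   # fail fast on unknown columns
  cfg
}

# validate gamma names against the columns the covariate set can produce;
# returns a function(data) -> latent mean vector
.check_gamma <- function(config) {
  freqs <- config$covariate_freqs
  valid <- "(Intercept)"
  ref <- list()
  for (v in names(freqs)) {
    levs <- names(freqs[[v]])
    ref[[v]] <- levs[length(levs)]
    valid <- c(valid, paste0(v, "=", levs[-length(levs)]))
  }
  unknown <- setdiff(names(config$gamma), valid)
  stopf(length(unknown) == 0L,
        "gamma names do not match design columns: %s",
        paste(unknown, collapse = ", "))
  function(data) {
    xg <- rep(0, nrow(data))
    for (j in names(config$gamma)) {
      g <- config$gamma[[j]]
      if (j == "(Intercept)") { xg <- xg + g; next }
      parts <- strsplit(j, "=", fixed = TRUE)[[1]]
      v <- parts[1]; lv <- paste(parts[-1], collapse = "=")
      code <- ifelse(data[[v]] == lv, 1,
                     ifelse(data[[v]] == ref[[v]], -1, 0))
      xg <- xg + g * code
    }
    xg
  }
}

#' Generate synthetic DBDC respondents
#'
#' Draws covariates from the configured category frequencies, latent WTP
#' pairs from the bivariate-normal error model, assigns each respondent an
#' initial bid uniformly at random from the schedule, and applies the DBDC
#' protocol: yes/no to the initial bid, then yes/no to the raised (after
#' yes) or lowered (after no) follow-up.  Output always satisfies the
#' respondent schema invariants and is deterministic given the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` if supplied.
#' @return validated respondent data frame (see [read_respondents()] for
#'   the schema).
#' @export
#' @examples
#' head(generate_respondents(synthetic_config(n = 20, seed = 1)))
generate_respondents <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  latent_mean <- .check_gamma(config)
  n <- config$n
  with_seed(seed, {
    data <- data.frame(id = sprintf("R%05d", seq_len(n)))
    for (v in names(config$covariate_freqs)) {
      p <- config$covariate_freqs[[v]]
      data[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    xg <- latent_mean(data)
    u1 <- stats::rnorm(n)
    u2 <- config$rho * u1 + sqrt(1 - config$rho^2) * stats::rnorm(n)
    wtp1 <- xg + config$sigma * u1
    wtp2 <- xg + config$sigma * u2
    bids <- config$bid_design$initial_bids
    data$bid1 <- bids[sample.int(length(bids), n, replace = TRUE)]
    data$z1 <- as.integer(wtp1 >= data$bid1)
    data$bid2 <- followup_bid(config$bid_design, data$bid1, data$z1)
    data$z2 <- as.integer(wtp2 >= data$bid2)
    validate_respondents(data[, .respondent_columns],
                         design = config$bid_design)
  })
}

#' Analytic response-pattern probabilities
#'
#' Closed-form probabilities of the four DBDC response patterns under the
#' latent bivariate-normal model, used as the generator's analytic oracle.
#' With `a(b) = (xgamma - b) / sigma`:
#' `P(YY) = Phi2(a(bid1), a(bid2_up); rho)`,
#' `P(YN) = Phi(a(bid1)) - P(YY)`,
#' `P(NY) = Phi(a(bid2_down)) - Phi2(a(bid1), a(bid2_down); rho)`,
#' `P(NN) = 1 - Phi(a(bid1)) - Phi(a(bid2_down)) +
#'          Phi2(a(bid1), a(bid2_down); rho)`.
#'
#' @param xgamma latent mean WTP (MYR).
#' @param sigma latent error SD, > 0.
#' @param rho latent error correlation.
#' @param bid1 initial bid.
#' @param bid2_up follow-up bid after a yes.
#' @param bid2_down follow-up bid after a no.
#' @return named numeric vector `c(YY, YN, NY, NN)` summing to 1.
#' @export
pattern_probabilities <- function(xgamma, sigma, rho, bid1,
                                  bid2_up = bid1 + 50,
                                  bid2_down = bid1 - 50) {
  stopf(is_number(sigma) && sigma > 0, "sigma must be > 0")
  stopf(is_number(rho) && abs(rho) <= 1, "|rho| must be <= 1")
  a1 <- (xgamma - bid1) / sigma
  a2u <- (xgamma - bid2_up) / sigma
  a2d <- (xgamma - bid2_down) / sigma
  yy <- bivariate_cdf(a1, a2u, rho)
  p1 <- stats::pnorm(a1)
  p2d <- stats::pnorm(a2d)
  both_no_compl <- bivariate_cdf(a1, a2d, rho)  # P(W1>=b1, W2>=b2d)
  c(YY = yy,
    YN = p1 - yy,
    NY = p2d - both_no_compl,
    NN = 1 - p1 - p2d + both_no_compl)
}
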