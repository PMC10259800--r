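#' Double-bounded bid schedule
#'
#' Defines the price design of a double-bounded dichotomous choice (DBDC)
#' survey: the set of initial bids one of which each respondent is shown, and
#' the fixed increment by which the follow-up bid is raised after a "yes" or
#' lowered after a "no".  The default schedule is seven initial bids from
#' MYR 100 to MYR 400 in steps of 50 with a MYR 50 follow-up increment.
#'
#' @param initial_bids strictly increasing vector of positive initial bids
#'   (MYR).
#' @param increment positive follow-up increment (MYR).  The lowest follow-up
#'   bid `min(initial_bids) - increment` must remain positive.
#' @param usd_rate USD per MYR conversion ratio.  Default `11.10 / 50`
#'   (= 0.222), the rate at which MYR 50 equals USD 11.10.
#' @return An object of class `bid_design`: a list with elements
#'   `initial_bids`, `increment`, `usd_rate`.
#' @seealso [followup_bid()], [myr_to_usd()], [read_bid_design()]
#' @export
#' @examples
#' bid_design()
bid_design <- function(initial_bids = seq(100, 400, by = 50),
                       increment = 50,
                       usd_rate = 11.10 / 50) {
  stopf(is.numeric(initial_bids) && length(initial_bids) >= 1L &&
          all(is.finite(initial_bids)), "initial_bids must be finite numbers")
  stopf(all(initial_bids > 0), "initial bids must be positive")
  stopf(!is.unsorted(initial_bids, strictly = TRUE),
        "initial bids must be strictly increasing")
  stopf(is_number(increment) && increment > 0, "increment must be positive")
  stopf(min(initial_bids) - increment > 0,
        "follow-up bid after a 'no' at the lowest initial bid would be <= 0")
  stopf(is_number(usd_rate) && usd_rate > 0, "usd_rate must be positive")
  structure(list(initial_bids = as.numeric(initial_bids),
                 increment = as.numeric(increment),
                 usd_rate = as.numeric(usd_rate)),
            class = "bid_design")
}

#' @export
print.bid_design <- function(x, ...) {
  cat("DBDC bid design\n")
  cat("  initial bids (MYR):", paste(x$initial_bids, collapse = ", "), "\n")
  cat("  follow-up increment (MYR):", x$increment, "\n")
  cat("  USD per MYR:", format(x$usd_rate), "\n")
  invisible(x)
}

#' Follow-up bid implied by the first response
#'
#' @param design a [bid_design()].
#' @param bid1 initial bid(s).
#' @param z1 first response(s), 1 = yes (bid raised), 0 = no (bid lowered).
#' @return numeric vector of follow-up bids.
#' @export
followup_bid <- function(design, bid1, z1) {
  stopifnot(inherits(design, "bid_design"))
  bid1 + ifelse(z1 == 1, design$increment, -design$increment)
}

#' Read a bid design from a YAML or JSON configuration file
#'
#' The file must contain keys `initial_bids`, `increment` and optionally
#' `usd_rate`.  Format is chosen by file extension (`.yml`/`.yaml` vs
#' `.json`).
#'
#' @param path path to the configuration file.
#' @return A [bid_design()].
#' @export
read_bid_design <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  stopf(!is.null(cfg$initial_bids) && !is.null(cfg$increment),
        "config must provide 'initial_bids' and 'increment'")
  bid_design(initial_bids = as.numeric(cfg$initial_bids),
             increment = as.numeric(cfg$increment),
             usd_rate = if (is.null(cfg$usd_rate)) 11.10 / 50
                        else as.numeric(cfg$usd_rate))
}

#' Convert MYR amounts to USD
#'
#' Multiplies by the exchange ratio and rounds half-up to 2 decimal places,
#' the convention used for published currency equivalences (e.g. MYR 460.23
#' at 0.222 USD/MYR is USD 102.17).
#'
#' @param amount amount(s) in MYR; negative amounts are an error.
#' @param rate USD per MYR ratio, default `11.10 / 50`.
#' @return amount(s) in USD, rounded to 2 dp.
#' @export
#' @examples
#' myr_to_usd(c(460.23, 394))
myr_to_usd <- function(amount, rate = 11.10 / 50) {
  stopf(is.numeric(amount) && all(is.finite(amount)), "amount must be numeric")
  stopf(all(amount >= 0), "negative MYR amount")
  stopf(is_number(rate) && rate > 0, "rate must be positive")
  round_half_up(amount * rate, 2)
}
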