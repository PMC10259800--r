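# Survey design arithmetic: sample size, stratum allocation, doubling.

#' Krejcie-Morgan sample size for a finite population
#'
#' Computes the required sample size
#' \deqn{s = \frac{z^2 p (1-p) / e^2}{1 + z^2 p (1-p) / (e^2 N)}}
#' i.e. the infinite-population size \eqn{z^2 p(1-p)/e^2} deflated by the
#' finite-population correction, rounded half-up to the nearest integer and
#' capped at the population size.  With the conventional inputs
#' (p = 0.5, e = 0.05, z = 1.96) and a large population this gives 384.
#'
#' @param N population size (>= 1).
#' @param p anticipated sample proportion, in (0, 1).  Default 0.5
#'   (maximises the required size).
#' @param e margin of error, in (0, 1).  Default 0.05.
#' @param z normal quantile for the confidence level.  Default 1.96 (95%).
#' @return integer sample size.
#' @export
#' @examples
#' krejcie_morgan(6509400)  # 384
krejcie_morgan <- function(N, p = 0.5, e = 0.05, z = 1.96) {
  stopf(is_number(N) && N >= 1, "N must be a positive population size")
  stopf(is_number(p) && p > 0 && p < 1, "p must lie in (0, 1)")
  stopf(is_number(e) && e > 0 && e < 1, "e must lie in (0, 1)")
  stopf(is_number(z) && z > 0, "z must be positive")
  s0 <- z^2 * p * (1 - p) / e^2
  s <- s0 / (1 + s0 / N)
  as.integer(min(round_half_up(s), N))
}

#' Proportional allocation by the largest-remainder (Hamilton) method
#'
#' Apportions `total_n` sampling units across strata in proportion to their
#' population sizes.  Each stratum first receives the floor of its exact
#' quota `total_n * pop / sum(pop)`; the remaining units go to the strata
#' with the largest fractional remainders, ties broken in favour of the
#' larger population.  The result always sums exactly to `total_n`, which
#' independent per-stratum rounding does not guarantee.
#'
#' @param populations positive stratum population sizes (any common scale).
#' @param total_n total sample size to allocate (>= 0).
#' @return integer vector of allocations, same length and names as
#'   `populations`, summing to `total_n`.
#' @export
#' @examples
#' # district populations ('000) with a 384-person total
#' pops <- c(sabak_bernam = 126.1, kuala_selangor = 251.2, klang = 1025.1,
#'           kuala_langat = 270.1, petaling = 2157, sepang = 256.9,
#'           ulu_langat = 1370.2, gombak = 815.2, ulu_selangor = 237.6)
#' allocate_proportional(pops, 384)
allocate_proportional <- function(populations, total_n) {
  stopf(is.numeric(populations) && length(populations) >= 1L,
        "populations must be a non-empty numeric vector")
  stopf(all(is.finite(populations)) && all(populations > 0),
        "populations must be positive")
  stopf(is_number(total_n) && total_n >= 0 && total_n == round(total_n),
        "total_n must be a non-negative integer")
  quota <- total_n * populations / sum(populations)
  alloc <- floor(quota)
  remainder <- quota - alloc
  left <- as.integer(round(total_n - sum(alloc)))
  if (left > 0L) {
    # order by remainder, then population size, both decreasing
    pick <- order(-remainder, -populations)[seq_len(left)]
    alloc[pick] <- alloc[pick] + 1
  }
  out <- as.integer(alloc)
  names(out) <- names(populations)
  out
}

#' Double a sample size
#'
#' Planned over-recruitment: field surveys often double the computed minimum
#' sample to absorb incomplete responses (384 doubled to 768).
#'
#' @param n sample size(s), non-negative integers.
#' @return `2 * n` as integer.
#' @export
double_sample <- function(n) {
  stopf(is.numeric(n) && all(is.finite(n)) && all(n >= 0) &&
          all(n == round(n)), "n must be non-negative integers")
  as.integer(2 * n)
}

#' Full stratified sample design
#'
#' Convenience wrapper combining [krejcie_morgan()], [allocate_proportional()]
#' and [double_sample()] into one design table.
#'
#' @param populations named positive stratum populations.
#' @param N total population size on the same individual scale used for the
#'   sample-size formula; defaults to `sum(populations)`.
#' @inheritParams krejcie_morgan
#' @return An object of class `sample_design`: a list with the allocation
#'   data frame (`strata`), `total_n` and `doubled_n`.
#' @export
sample_design <- function(populations, N = sum(populations),
                          p = 0.5, e = 0.05, z = 1.96) {
  total_n <- krejcie_morgan(N, p = p, e = e, z = z)
  alloc <- allocate_proportional(populations, total_n)
  strata <- data.frame(
    stratum = if (is.null(names(populations)))
      paste0("stratum", seq_along(populations)) else names(populations),
    population = as.numeric(populations),
    proportion = as.numeric(populations) / sum(populations),
    sample = as.integer(alloc),
    doubled = double_sample(alloc),
    row.names = NULL
  )
  structure(list(strata = strata,
                 total_n = total_n,
                 doubled_n = double_sample(total_n)),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, digits = 2, ...) {
  cat("Stratified sample design (Krejcie-Morgan + largest remainder)\n")
  df <- x$strata
  df$proportion <- round(df$proportion, digits)
  print(df, row.names = FALSE)
  cat("Total:", x$total_n, " Doubled:", x$doubled_n, "\n")
  invisible(x)
}
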