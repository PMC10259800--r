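# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the published percentage and
#' currency figures.  Base R's `round()` rounds half to even, which would turn
#' e.g. 0.5 into 0 and disagree with printed survey tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, ties going away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.25, -0.5), c(0, 1, 0))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# is x a single finite number?
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# error unless cond, with sprintf-style message
stopf <- function(cond, fmt, ...) if (!cond) stop(sprintf(fmt, ...), call. = FALSE)

# run expr with a private RNG stream seeded by `seed` (NULL = use current
# stream); the caller's .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
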