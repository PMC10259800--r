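# Effects coding and design-matrix construction for the probit models.

#' Effects-code categorical covariates
#'
#' Deviation (sum-to-zero) coding: a covariate with k levels contributes
#' k - 1 columns, one per non-reference level, holding 1 for that level,
#' -1 for the reference level and 0 otherwise.  The implied effect of the
#' reference level is minus the sum of the estimated level effects, so all
#' k effects sum to zero.  Columns are named `covariate=level`.
#'
#' @param data data frame containing the covariates (factors or character).
#' @param covariates character vector of covariate column names.
#' @param reference optional named character vector/list mapping covariate
#'   name to its reference level; by default the last level (factor order,
#'   else sorted unique order) is the reference.
#' @return numeric matrix with one row per observation and attributes
#'   `levels` (list of level vectors, reference last) and `reference`
#'   (named character vector).
#' @export
#' @examples
#' d <- data.frame(edu = c("A", "B", "C"))
#' encode_effects(d, "edu", reference = c(edu = "C"))
encode_effects <- function(data, covariates, reference = NULL) {
  stopifnot(is.data.frame(data))
  stopf(all(covariates %in% names(data)), "covariate(s) not in data: %s",
        paste(setdiff(covariates, names(data)), collapse = ", "))
  cols <- list()
  lev_out <- list()
  ref_out <- character(0)
  for (v in covariates) {
    x <- data[[v]]
    levs <- if (is.factor(x)) levels(x)[levels(x) %in% unique(as.character(x))]
            else sort(unique(as.character(x)))
    x <- as.character(x)
    stopf(length(levs) >= 2L,
          "covariate '%s' has a single observed level", v)
    ref <- if (!is.null(reference) && v %in% names(reference))
      as.character(reference[[v]]) else levs[length(levs)]
    stopf(ref %in% levs, "reference level '%s' not observed for '%s'",
          ref, v)
    levs <- c(setdiff(levs, ref), ref)   # reference last
    for (lv in levs[-length(levs)]) {
      col <- ifelse(x == lv, 1, ifelse(x == ref, -1, 0))
      cols[[paste0(v, "=", lv)]] <- col
    }
    lev_out[[v]] <- levs
    ref_out[v] <- ref
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  attr(X, "levels") <- lev_out
  attr(X, "reference") <- ref_out
  X
}

#' Implied effect of the reference levels
#'
#' Under effects coding the reference-level effect is not estimated directly;
#' it equals minus the sum of the estimated effects of the other levels of
#' the same covariate.
#'
#' @param coefficients named coefficient vector over `covariate=level`
#'   columns (extra entries such as the intercept or bid are ignored).
#' @param covariate covariate name.
#' @return the implied reference-level effect (numeric scalar).
#' @export
reference_effect <- function(coefficients, covariate) {
  idx <- grepl(paste0("^", covariate, "="), names(coefficients))
  stopf(any(idx), "no effects-coded columns found for '%s'", covariate)
  -sum(coefficients[idx])
}

#' Build a probit design matrix
#'
#' Assembles intercept, optional bid column and effects-coded covariates
#' into the design used by [fit_probit()] and [fit_bivariate_probit()].
#' The column means of the non-bid columns (with 1 for the intercept) are
#' retained as `xbar`, the row vector used in the closed-form mean-WTP
#' expression.
#'
#' @inheritParams encode_effects
#' @param bid name of the bid column to include as the price variable, or
#'   `NULL` for a design without a price term.
#' @return An object of class `dbdc_design`: list with elements `X` (numeric
#'   matrix, first column `(Intercept)`), `bid_name`, `xbar` (named means of
#'   the non-bid columns) and the effects-coding metadata.
#' @export
design_matrix <- function(data, bid = "bid1", covariates = character(0),
                          reference = NULL) {
  n <- nrow(data)
  parts <- list(`(Intercept)` = rep(1, n))
  if (!is.null(bid)) {
    stopf(bid %in% names(data), "bid column '%s' not in data", bid)
    stopf(is.numeric(data[[bid]]), "bid column '%s' must be numeric", bid)
    parts[[bid]] <- as.numeric(data[[bid]])
  }
  E <- NULL
  if (length(covariates) > 0L) {
    E <- encode_effects(data, covariates, reference)
    for (j in colnames(E)) parts[[j]] <- E[, j]
  }
  X <- do.call(cbind, parts)
  xbar <- colMeans(X[, setdiff(colnames(X), bid), drop = FALSE])
  structure(list(X = X,
                 bid_name = if (is.null(bid)) NULL else bid,
                 xbar = xbar,
                 levels = if (is.null(E)) list() else attr(E, "levels"),
                 reference = if (is.null(E)) character(0)
                             else attr(E, "reference")),
            class = "dbdc_design")
}

#' @export
print.dbdc_design <- function(x, ...) {
  cat("DBDC design matrix:", nrow(x$X), "rows,", ncol(x$X), "columns\n")
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  if (!is.null(x$bid_name)) cat("  bid variable:", x$bid_name, "\n")
  invisible(x)
}

# coerce a dbdc_design or plain matrix to the model matrix
.as_model_matrix <- function(design) {
  if (inherits(design, "dbdc_design")) design$X
  else if (is.matrix(design)) design
  else stop("design must be a dbdc_design or a numeric matrix",
            call. = FALSE)
}
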