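# Descriptive outputs: response distribution, association screening, VIF.

#' Tabulate the DBDC response distribution
#'
#' Counts the four response patterns (YY, YN, NY, NN) per initial bid, with
#' row totals and a grand-total row.  Cell percentages are computed within
#' each bid row (count / row total); the total-row percentages are shares of
#' the grand total.  All percentages are rounded half-up to 1 decimal
#' place.
#'
#' @param data validated respondent data frame.
#' @return object of class `response_table`: a data frame with one row per
#'   observed initial bid plus a `Total` row, and columns `bid`, the four
#'   pattern counts, their percentages (`*_pct`) and `total`.
#' @export
tabulate_responses <- function(data) {
  stopf(nrow(data) > 0, "empty respondent table")
  pat <- response_pattern(data$z1, data$z2)
  tab <- table(bid = factor(data$bid1), pattern = pat)
  counts <- as.data.frame.matrix(tab)
  bid <- as.numeric(rownames(counts))
  row_total <- rowSums(counts)
  grand <- colSums(counts)
  n <- sum(grand)
  out <- data.frame(bid = c(bid, NA),
                    YY = c(counts$YY, grand["YY"]),
                    YN = c(counts$YN, grand["YN"]),
                    NY = c(counts$NY, grand["NY"]),
                    NN = c(counts$NN, grand["NN"]),
                    total = c(row_total, n), row.names = NULL)
  denom <- c(row_total, rep(n, 1))
  for (p in c("YY", "YN", "NY", "NN"))
    out[[paste0(p, "_pct")]] <- round_half_up(100 * out[[p]] / denom, 1)
  out$total_pct <- round_half_up(100 * out$total / n, 1)
  out$label <- c(paste0("RM", bid), "Total")
  structure(out, class = c("response_table", "data.frame"))
}

#' @export
print.response_table <- function(x, ...) {
  df <- data.frame(
    `Initial bid` = x$label,
    `Yes-Yes` = sprintf("%d (%.1f%%)", x$YY, x$YY_pct),
    `Yes-No` = sprintf("%d (%.1f%%)", x$YN, x$YN_pct),
    `No-Yes` = sprintf("%d (%.1f%%)", x$NY, x$NY_pct),
    `No-No` = sprintf("%d (%.1f%%)", x$NN, x$NN_pct),
    Obs = x$total, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Chi-square screening of covariate/response association
#'
#' Pearson chi-square test (no continuity correction) of the contingency
#' table between a categorical covariate and a binary response: the first
#' answer (`"single"`-bounded response, `z1`) or the second
#' (`"double"`-bounded, `z2`).  Used to screen candidate covariates before
#' the probit models.
#'
#' @param data respondent data frame.
#' @param covariate name of a categorical column.
#' @param response `"single"` (z1), `"double"` (z2), or a numeric vector.
#' @return list with `statistic`, `df`, `p.value` and the contingency
#'   `table`.
#' @export
chisq_association <- function(data, covariate,
                              response = c("single", "double")) {
  stopf(covariate %in% names(data), "no column '%s'", covariate)
  z <- if (is.character(response) || is.factor(response)) {
    switch(match.arg(response), single = data$z1, double = data$z2)
  } else response
  x <- factor(data[[covariate]])
  x <- droplevels(x)
  tab <- table(x, factor(z))
  stopf(nrow(tab) >= 2 && ncol(tab) >= 2,
        "contingency table is degenerate (needs >= 2 rows and columns)")
  stopf(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
        "contingency table has an empty margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value), table = tab)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from the least-squares regression of each
#' non-intercept design column on all the others (with intercept), plus the
#' mean VIF across those columns — the usual multicollinearity screen
#' before a regression model.  Exactly collinear columns are reported as
#' infinite and named.
#'
#' @param design a [design_matrix()] or numeric matrix including an
#'   `(Intercept)` column.
#' @return list with `vif` (named vector) and `mean_vif`.
#' @export
vif <- function(design) {
  X <- .as_model_matrix(design)
  cols <- setdiff(colnames(X), "(Intercept)")
  stopf(length(cols) >= 2, "need at least 2 non-intercept columns")
  out <- numeric(length(cols))
  names(out) <- cols
  for (j in cols) {
    y <- X[, j]
    Xo <- X[, setdiff(colnames(X), j), drop = FALSE]
    fit <- stats::lm.fit(Xo, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    stopf(tss > 0, "column '%s' is constant", j)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out)))
    warning(sprintf("exact collinearity in column(s): %s",
                    paste(names(out)[!is.finite(out)], collapse = ", ")))
  list(vif = out, mean_vif = mean(out))
}
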