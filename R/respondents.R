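# Respondent records: CSV schema, validation, WTP bound intervals.

#' Default category levels for the respondent schema
#'
#' Named list giving, for each categorical covariate, its admissible labels
#' in display order.  The last level of each covariate is the default
#' reference level for effects coding (see [encode_effects()]).
#'
#' @return named list of character vectors.
#' @export
dbdc_levels <- function() {
  list(
    district = c("sabak-bernam", "kuala-selangor", "klang", "kuala-langat",
                 "petaling", "sepang", "ulu-langat", "gombak",
                 "ulu-selangor"),
    gender = c("male", "female"),
    age_band = c("20-30", "31-40", "41-50", "51-60"),
    ethnicity = c("malay", "chinese", "indian", "other"),
    education = c("high-school-or-below", "certificate-or-diploma",
                  "bachelor", "postgraduate"),
    income_band = c("<1000", "1001-3000", "3001-5000", "5001-7000", ">=7001")
  )
}

.respondent_columns <- c("id", "district", "gender", "age_band", "ethnicity",
                         "education", "income_band", "bid1", "z1", "bid2",
                         "z2")

# normalise a label: trim whitespace, lower-case
.norm_label <- function(x) tolower(trimws(as.character(x)))

#' Validate a respondent table
#'
#' Checks the DBDC respondent schema: required columns present, responses
#' binary, category labels known (matched case-insensitively after
#' trimming), initial bids on the design schedule, and the follow-up rule
#' `bid2 = bid1 + increment` after a yes / `bid1 - increment` after a no,
#' with `bid2 > 0`.  Any violation is an error naming the offending rows;
#' rows are never silently dropped.
#'
#' @param data data frame of respondent records.
#' @param design a [bid_design()].
#' @param levels admissible category labels, as from [dbdc_levels()].
#' @return the validated data frame, invisibly, with category columns
#'   normalised to lower case and coded as factors in schema order.
#' @export
validate_respondents <- function(data, design = bid_design(),
                                 levels = dbdc_levels()) {
  stopifnot(is.data.frame(data), inherits(design, "bid_design"))
  missing_cols <- setdiff(.respondent_columns, names(data))
  stopf(length(missing_cols) == 0L, "missing columns: %s",
        paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  stopf(n > 0L, "empty respondent table")

  bad_rows <- function(idx, what) {
    stopf(!any(idx), "%s in row(s): %s", what,
          paste(utils::head(which(idx), 20), collapse = ", "))
  }
  for (v in names(levels)) {
    lab <- .norm_label(data[[v]])
    bad_rows(!(lab %in% levels[[v]]), sprintf("unknown %s label", v))
    data[[v]] <- factor(lab, levels = levels[[v]])
  }
  for (v in c("z1", "z2")) {
    bad_rows(!(data[[v]] %in% c(0, 1)), sprintf("non-binary %s", v))
    data[[v]] <- as.integer(data[[v]])
  }
  bad_rows(!(data$bid1 %in% design$initial_bids),
           "bid1 not on the design schedule")
  expected_bid2 <- followup_bid(design, data$bid1, data$z1)
  bad_rows(data$bid2 != expected_bid2,
           "bid2 inconsistent with z1 and the follow-up rule")
  bad_rows(data$bid2 <= 0, "non-positive bid2")
  invisible(data)
}

#' Read respondent records from CSV
#'
#' Reads a comma-separated, UTF-8, headered file with columns
#' `id, district, gender, age_band, ethnicity, education, income_band,
#' bid1, z1, bid2, z2` (money as plain MYR numbers) and validates it with
#' [validate_respondents()].
#'
#' @inheritParams validate_respondents
#' @param path path to the CSV file.
#' @return validated data frame of respondents.
#' @export
read_respondents <- function(path, design = bid_design(),
                             levels = dbdc_levels()) {
  stopf(file.exists(path), "no such file: %s", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  validate_respondents(data, design = design, levels = levels)
}

#' Write respondent records to CSV
#'
#' Deterministic plain-text writer (no quoting of numerics, no row names) so
#' that identical tables produce byte-identical files.
#'
#' @param data respondent data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_respondents <- function(data, path) {
  out <- data
  for (v in names(out)) if (is.factor(out[[v]])) out[[v]] <- as.character(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Response pattern of each respondent
#'
#' @param z1,z2 binary response vectors.
#' @return factor with levels `YY`, `YN`, `NY`, `NN`.
#' @export
response_pattern <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  factor(paste0(ifelse(z1 == 1, "Y", "N"), ifelse(z2 == 1, "Y", "N")),
         levels = c("YY", "YN", "NY", "NN"))
}

#' WTP interval bounds implied by the response pattern
#'
#' The two answers bound each respondent's latent willingness to pay:
#' \describe{
#'   \item{YY}{`[bid2, Inf)` — accepted the raised follow-up}
#'   \item{YN}{`[bid1, bid2)` — accepted the initial bid, refused the raise}
#'   \item{NY}{`[bid2, bid1)` — refused the initial bid, accepted the cut}
#'   \item{NN}{`[floor, bid2)` — refused both; `floor` is the lower
#'     truncation point, 0 by default (negative WTP for a vaccine treated as
#'     economically meaningless) or `-Inf` if negative WTP is admitted}
#' }
#' For any initial bid, the four intervals partition `[floor, Inf)`.
#'
#' @param data validated respondent data frame (needs `bid1`, `z1`, `bid2`,
#'   `z2`).
#' @param floor lower truncation for the NN interval; default 0.
#' @return data frame with columns `lower`, `upper`, `pattern`.
#' @export
#' @examples
#' d <- data.frame(bid1 = c(100, 100, 200), z1 = c(1, 0, 1),
#'                 bid2 = c(150, 50, 250), z2 = c(1, 0, 0))
#' wtp_bounds(d)
wtp_bounds <- function(data, floor = 0) {
  stopifnot(all(c("bid1", "z1", "bid2", "z2") %in% names(data)))
  stopf(is_number(floor) || identical(floor, -Inf),
        "floor must be a number or -Inf")
  pat <- response_pattern(data$z1, data$z2)
  lower <- ifelse(pat == "YY", data$bid2,
           ifelse(pat == "YN", data$bid1,
           ifelse(pat == "NY", data$bid2, floor)))
  upper <- ifelse(pat == "YY", Inf,
           ifelse(pat == "NN", data$bid2,
           ifelse(pat == "YN", data$bid2, data$bid1)))
  out <- data.frame(lower = lower, upper = upper, pattern = pat)
  stopifnot(all(out$lower <= out$upper))
  out
}
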