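#' Fruit availability index for one monthly census
#'
#' FAI is the percent of censused stems with diameter at breast height
#' (dbh) strictly greater than 10 cm that carry fruit. Stems at or below
#' 10 cm are excluded from numerator and denominator alike.
#'
#' @param census data.frame with columns `dbh_cm` (> 0) and `fruiting`
#'   (logical or 0/1) for a single month.
#' @param dbh_threshold_cm Size threshold; default 10, applied strictly.
#' @return FAI as a percent in \[0, 100\].
#' @export
#' @examples
#' census <- data.frame(dbh_cm = c(12, 15, 8), fruiting = c(1, 0, 1))
#' compute_fai(census) # 50: the 8 cm stem is ignored
compute_fai <- function(census, dbh_threshold_cm = 10) {
  stopifnot(all(c("dbh_cm", "fruiting") %in% names(census)))
  if (any(census$dbh_cm <= 0)) {
    elbm_error("dbh_cm must be > 0 for every stem", "elbm_validation_error")
  }
  big <- census$dbh_cm > dbh_threshold_cm
  if (!any(big)) {
    elbm_error(
      paste0("FAI undefined: no stems with dbh > ", dbh_threshold_cm, " cm"),
      "elbm_undefined_index_error"
    )
  }
  100 * sum(census$fruiting[big] > 0) / sum(big)
}

#' Monthly FAI series from a phenology table
#'
#' Applies [compute_fai()] to each month of a long-format census table.
#'
#' @param phenology data.frame with columns `month` (`"YYYY-MM"`),
#'   `stem_id`, `dbh_cm`, `fruiting`.
#' @param dbh_threshold_cm Passed to [compute_fai()].
#' @return data.frame of class `elbm_fai_series` with columns `month` and
#'   `fai_percent`, ordered by month.
#' @export
fai_series <- function(phenology, dbh_threshold_cm = 10) {
  stopifnot(all(c("month", "dbh_cm", "fruiting") %in% names(phenology)))
  if (any(duplicated(phenology[, c("month", "stem_id")]))) {
    elbm_error("stem_id must be unique within each month", "elbm_validation_error")
  }
  months <- sort(unique(phenology$month))
  fai <- vapply(months, function(m) {
    compute_fai(phenology[phenology$month == m, , drop = FALSE], dbh_threshold_cm)
  }, numeric(1))
  structure(
    data.frame(month = months, fai_percent = unname(fai),
               stringsAsFactors = FALSE),
    class = c("elbm_fai_series", "data.frame")
  )
}

#' Split an FAI series into high and low fruit periods
#'
#' Labels each month relative to the sample median of the monthly FAI
#' values. Under the default `"strict_greater"` rule a month is `"high"`
#' iff its FAI strictly exceeds the median; months at exactly the median
#' are `"low"`. The `"greater_equal"` rule labels months at the median
#' `"high"` instead.
#'
#' @param series An `elbm_fai_series` (or data.frame with `month`,
#'   `fai_percent`).
#' @param tie_rule `"strict_greater"` (default) or `"greater_equal"`.
#' @return The series with added `fai_label` column (factor, levels
#'   `high`, `low`) and a `median_fai` attribute.
#' @export
binarize_fai <- function(series, tie_rule = c("strict_greater", "greater_equal")) {
  tie_rule <- match.arg(tie_rule)
  if (is.null(series) || nrow(series) == 0) {
    elbm_error("empty FAI series", "elbm_validation_error")
  }
  if (nrow(series) < 2) {
    elbm_error("need >= 2 months to binarize FAI", "elbm_validation_error")
  }
  med <- median(series$fai_percent)
  hi <- if (tie_rule == "strict_greater") {
    series$fai_percent > med
  } else {
    series$fai_percent >= med
  }
  series$fai_label <- factor(ifelse(hi, "high", "low"), levels = c("high", "low"))
  attr(series, "median_fai") <- med
  class(series) <- unique(c("elbm_fai_series", class(series)))
  series
}

#' Attach monthly FAI to urine samples
#'
#' Joins FAI (and the high/low label when present) to each sample by its
#' calendar month of collection. Sample rows are preserved unchanged
#' apart from the added columns.
#'
#' @param samples Urine-sample data.frame with a `date` column
#'   (`"YYYY-MM-DD"`).
#' @param series FAI series, labelled via [binarize_fai()] if labels are
#'   wanted.
#' @return `samples` with added `month`, `fai_percent` and (if available)
#'   `fai_label` columns.
#' @export
attach_fai <- function(samples, series) {
  month <- substr(as.character(samples$date), 1, 7)
  missing_months <- setdiff(unique(month), series$month)
  if (length(missing_months) > 0) {
    elbm_error(
      paste0("sample month(s) absent from FAI series: ",
             paste(sort(missing_months), collapse = ", ")),
      "elbm_missing_month_error"
    )
  }
  idx <- match(month, series$month)
  samples$month <- month
  samples$fai_percent <- series$fai_percent[idx]
  if ("fai_label" %in% names(series)) {
    samples$fai_label <- series$fai_label[idx]
  }
  samples
}
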