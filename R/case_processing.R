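#' SPSS-style case-processing summary
#'
#' Classifies every case of the cohort the way the classic survival-analysis
#' case-processing table does: cases available for analysis (events and
#' censored), cases dropped for missing covariate values (listwise), and
#' censored cases whose follow-up ends before the earliest event in their
#' stratum (which contribute nothing to the partial likelihood and are
#' reported as unused). Percentages are of the grand total, rounded half away
#' from zero to one decimal.
#'
#' @param cohort cohort data frame.
#' @param endpoint see [endpoint_status()].
#' @param covariates covariates required for the analysis; defaults to every
#'   column except `case_id`, `time_months`, `event`, `cause`.
#' @param strata optional name of a stratification column; the
#'   earliest-event rule is then applied within each stratum.
#' @return An object of class `"case_processing"`; see
#'   [case_processing_from_counts()] for the fields.
#' @export
case_processing_summary <- function(cohort, endpoint = "overall",
                                    covariates = NULL, strata = NULL) {
  if (!nrow(cohort)) stop("empty cohort")
  es <- endpoint_status(cohort, endpoint)
  if (is.null(covariates)) {
    covariates <- setdiff(names(cohort),
                          c("case_id", "time_months", "event", "cause"))
  }
  miss_cols <- setdiff(covariates, names(cohort))
  if (length(miss_cols)) stop("cohort lacks covariate(s): ",
                              paste(miss_cols, collapse = ", "))
  cov_df <- cohort[, covariates, drop = FALSE]
  is_missing <- !stats::complete.cases(cov_df) | is.na(es$time) | is.na(es$status)

  strat <- if (is.null(strata)) rep(1L, nrow(cohort)) else cohort[[strata]]
  early <- rep(FALSE, nrow(cohort))
  for (g in unique(strat[!is_missing])) {
    in_g <- !is_missing & strat == g
    ev_times <- es$time[in_g & es$status == 1]
    if (!length(ev_times)) next
    early[in_g & es$status == 0 & es$time < min(ev_times)] <- TRUE
  }
  n_event <- sum(!is_missing & es$status == 1)
  n_early <- sum(early)
  n_censored <- sum(!is_missing & es$status == 0) - n_early
  n_missing <- sum(is_missing)
  out <- case_processing_from_counts(n_event, n_censored, n_missing, n_early)
  out$endpoint <- es$endpoint
  out
}

#' Case-processing summary from raw counts
#'
#' Builds the report table directly from the four class counts; the grand
#' total is their sum. Percentages are `100 * count / grand total`, rounded
#' half away from zero to one decimal; the printed rendering suppresses the
#' leading zero for values below 1 (".4%").
#'
#' @param n_event events available for analysis.
#' @param n_censored censored cases available for analysis.
#' @param n_missing cases excluded for missing covariate values.
#' @param n_early censored cases preceding the earliest event in their
#'   stratum.
#' @return An object of class `"case_processing"`: a list with `counts`
#'   (named integer vector including the subtotals `available` and `unused`
#'   and the grand `total`), `percent` (matching rounded percentages) and
#'   `table` (data frame rendering).
#' @export
#' @examples
#' cp <- case_processing_from_counts(81, 150, 12, 1)
#' cp$percent[["event"]]      # 33.2
#' cp$percent[["available"]]  # 94.7
#' print(cp)
case_processing_from_counts <- function(n_event, n_censored, n_missing = 0,
                                        n_early = 0) {
  stopifnot(n_event >= 0, n_censored >= 0, n_missing >= 0, n_early >= 0)
  counts <- c(event = n_event, censored = n_censored,
              available = n_event + n_censored,
              missing = n_missing, early_censored = n_early,
              unused = n_missing + n_early,
              total = n_event + n_censored + n_missing + n_early)
  if (counts[["total"]] == 0) stop("all counts are zero")
  percent <- round_half_away(100 * counts / counts[["total"]], 1)
  tab <- data.frame(
    class = c("Cases available for analysis: event",
              "Cases available for analysis: censored",
              "Cases available for analysis: total",
              "Unused cases: missing values",
              "Unused cases: censored prior to earliest event in stratum",
              "Unused cases: total",
              "Total"),
    n = as.integer(counts),
    percent = as.numeric(percent),
    rendered = format_percent(as.numeric(percent))
  )
  structure(list(counts = counts, percent = percent, table = tab,
                 endpoint = NA_character_),
            class = "case_processing")
}

#' @export
print.case_processing <- function(x, ...) {
  cat("Evaluation of the case processing",
      if (!is.na(x$endpoint)) sprintf(" (%s survival)", sub("_", "-", x$endpoint)),
      "\n", sep = "")
  w <- max(nchar(x$table$class)) + 2
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-*s %5d  %7s\n", w, x$table$class[i], x$table$n[i],
                x$table$rendered[i]))
  }
  invisible(x)
}

#' Write a case-processing summary to CSV
#'
#' @param x a `"case_processing"`.
#' @param path output file.
#' @export
write_case_processing_csv <- function(x, path) {
  stopifnot(inherits(x, "case_processing"))
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
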