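#' Construct a symptom series
#'
#' One patient's irregular time series of self-reported UPDRS Parts I+II
#' totals.  Reports sharing a timestamp are collapsed to a single report with
#' the half-up-rounded mean score (the trend smoother requires distinct
#' times); out-of-order input is sorted by time.
#'
#' @param patient_id single string identifier.
#' @param times numeric vector, years since diagnosis (>= 0).
#' @param scores integer vector of Parts I+II totals in \[0, 68\].
#' @param labels per-report treatment label, each one of `"on"`, `"off"`,
#'   `"unknown"`.  Defaults to all `"unknown"`.
#' @param age_at_diagnosis optional age in years.
#' @param sex optional `"female"`/`"male"`.
#' @return object of class `symptom_series` with fields `patient_id`,
#'   `times`, `scores`, `labels` and the optional demographics.
#' @export
symptom_series <- function(patient_id, times, scores, labels = NULL,
                           age_at_diagnosis = NULL, sex = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1L || is.na(patient_id))
    stop_field("patient_id", "must be a single string")
  times <- as.numeric(times)
  scores <- as.numeric(scores)
  n <- length(times)
  if (n < 1L) stop_field("times", "must contain at least one report")
  if (length(scores) != n)
    stop_field("scores", "must have the same length as `times`")
  if (is.null(labels)) labels <- rep("unknown", n)
  if (length(labels) != n)
    stop_field("labels", "must have the same length as `times`")
  if (!all(labels %in% c("on", "off", "unknown")))
    stop_field("labels", "values must be 'on', 'off' or 'unknown'")
  if (any(!is.finite(times)) || any(times < 0))
    stop_field("times", "must be finite and >= 0 (years since diagnosis)")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 68) ||
      any(scores != floor(scores)))
    stop_field("scores", "must be integers in [0, 68]")

  ord <- order(times)
  times <- times[ord]; scores <- scores[ord]; labels <- labels[ord]
  if (anyDuplicated(times)) {
    grp <- match(times, unique(times))
    scores <- as.numeric(tapply(scores, grp, function(s) round_half_up(mean(s))))
    labels <- as.character(tapply(labels, grp, function(l) l[[1L]]))
    times <- unique(times)
  }
  structure(
    list(patient_id = patient_id, times = times, scores = as.integer(scores),
         labels = labels, age_at_diagnosis = age_at_diagnosis, sex = sex),
    class = "symptom_series")
}

#' @export
print.symptom_series <- function(x, ...) {
  cat(sprintf("<symptom_series> patient %s: %d reports over %.2f-%.2f yr\n",
              x$patient_id, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Construct a cohort from symptom series
#'
#' @param series list of [symptom_series()] objects with distinct ids.
#' @return object of class `pd_cohort` (a named list of series).
#' @export
pd_cohort <- function(series) {
  if (!is.list(series) || !all(vapply(series, inherits, TRUE, "symptom_series")))
    stop_field("series", "must be a list of symptom_series objects")
  ids <- vapply(series, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop_field("series", "patient ids must be distinct")
  structure(setNames(series, ids), class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  n_rep <- vapply(x, function(s) length(s$times), 0L)
  cat(sprintf("<pd_cohort> %d patients, %d reports (%.1f per patient)\n",
              length(x), sum(n_rep), mean(n_rep)))
  invisible(x)
}

#' Sum UPDRS Part I and Part II item responses
#'
#' Part I (mentation, behavior, mood) has 4 items and Part II (activities of
#' daily living) has 13 items, each scored 0 (no symptoms) to 4 (severe), so
#' the combined total ranges from 0 to 68.
#'
#' @param part1_items integer vector of exactly 4 item scores in \[0, 4\].
#' @param part2_items integer vector of exactly 13 item scores in \[0, 4\].
#' @return integer total in \[0, 68\].
#' @examples
#' score_parts_1_2(rep(4, 4), rep(4, 13))  # 68, the subscale maximum
#' @export
score_parts_1_2 <- function(part1_items, part2_items) {
  if (length(part1_items) != 4L)
    stop_field("part1_items", "must contain exactly 4 items")
  if (length(part2_items) != 13L)
    stop_field("part2_items", "must contain exactly 13 items")
  items <- c(part1_items, part2_items)
  if (any(!is.finite(items)) || any(items != floor(items)) ||
      any(items < 0 | items > 4))
    stop_field("items", "each item must be an integer in [0, 4]")
  as.integer(sum(items))
}

#' Mean reporting interval of a series, in days
#'
#' Span from first to last report divided by the number of gaps:
#' `(t_last - t_first) * 365.25 / (n - 1)`.  `NA` for a single report.
#'
#' @param series a [symptom_series()].
#' @return mean consecutive-report interval in days.
#' @export
mean_report_interval_days <- function(series) {
  n <- length(series$times)
  if (n < 2L) return(NA_real_)
  (series$times[n] - series$times[1L]) * DAYS_PER_YEAR / (n - 1)
}

#' Apply the reporting-frequency inclusion filter
#'
#' A patient is included iff they have at least `min_reports` reports and a
#' mean consecutive-report interval of at most `max_mean_interval_days`
#' (both boundaries inclusive).  Single-report series have an undefined mean
#' interval and are excluded: as `too_few_reports` when `min_reports > 1`,
#' otherwise as `interval_too_long`.
#'
#' @param cohort a [pd_cohort()].
#' @param min_reports minimum report count (default 15).
#' @param max_mean_interval_days maximum mean interval in days (default 65).
#' @return object of class `filter_report`: `included` (ids), `excluded`
#'   (data frame id/reason with reasons `too_few_reports`,
#'   `interval_too_long`), and `stats` (per-patient count and mean interval).
#' @export
apply_inclusion_filter <- function(cohort, min_reports = 15,
                                   max_mean_interval_days = 65) {
  stopifnot(inherits(cohort, "pd_cohort"))
  min_reports <- check_count(min_reports, "min_reports", min = 1)
  max_mean_interval_days <- check_positive(max_mean_interval_days,
                                           "max_mean_interval_days")
  ids <- names(cohort)
  n_reports <- vapply(cohort, function(s) length(s$times), 0L)
  mean_int <- vapply(cohort, mean_report_interval_days, 0)
  reason <- rep(NA_character_, length(ids))
  reason[!is.na(mean_int) & mean_int > max_mean_interval_days] <-
    "interval_too_long"
  reason[is.na(mean_int) & min_reports <= 1L] <- "interval_too_long"
  reason[n_reports < min_reports] <- "too_few_reports"
  included <- ids[is.na(reason)]
  excluded <- data.frame(patient_id = ids[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  structure(
    list(included = included, excluded = excluded,
         stats = data.frame(patient_id = ids, n_reports = n_reports,
                            mean_interval_days = mean_int,
                            included = is.na(reason),
                            row.names = NULL, stringsAsFactors = FALSE),
         min_reports = min_reports,
         max_mean_interval_days = max_mean_interval_days),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d included, %d excluded (>= %d reports, mean interval <= %g d)\n",
              length(x$included), nrow(x$excluded), x$min_reports,
              x$max_mean_interval_days))
  invisible(x)
}

#' Subset a cohort to the patients retained by a filter report
#'
#' @param cohort a [pd_cohort()].
#' @param report a `filter_report` from [apply_inclusion_filter()].
#' @return filtered [pd_cohort()].
#' @export
filter_cohort <- function(cohort, report) {
  stopifnot(inherits(cohort, "pd_cohort"), inherits(report, "filter_report"))
  pd_cohort(unname(cohort[report$included]))
}

#' Convert a cohort to a long data frame
#'
#' @param cohort a [pd_cohort()].
#' @return data frame with columns `patient_id`, `t_years`, `updrs_1_2`,
#'   `label`, one row per report.
#' @export
cohort_to_df <- function(cohort) {
  stopifnot(inherits(cohort, "pd_cohort"))
  do.call(rbind, lapply(unname(cohort), function(s) {
    data.frame(patient_id = s$patient_id, t_years = s$times,
               updrs_1_2 = s$scores, label = s$labels,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to CSV (long format)
#'
#' Columns `patient_id,t_years,updrs_1_2,label`; times are written with 17
#' significant digits so that write/read round-trips losslessly.
#'
#' @param cohort a [pd_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cohort_to_df(cohort)
  df$t_years <- sprintf("%.17g", df$t_years)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV (long format)
#'
#' Expects header `patient_id,t_years,updrs_1_2,label`.  Rows are grouped by
#' patient and sorted by time (with a warning if input rows were out of
#' order); malformed rows are rejected with their line number (line 1 is the
#' header).
#'
#' @param path CSV file path.
#' @return a [pd_cohort()].
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("patient_id", "t_years", "updrs_1_2", "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  t_years <- suppressWarnings(as.numeric(df$t_years))
  bad <- which(!is.finite(t_years))
  if (length(bad))
    stop(sprintf("non-numeric t_years on line %d", line_no[bad[1L]]),
         call. = FALSE)
  score <- suppressWarnings(as.numeric(df$updrs_1_2))
  bad <- which(!is.finite(score) | score != floor(score) |
                 score < 0 | score > 68)
  if (length(bad))
    stop(sprintf("invalid updrs_1_2 (must be an integer in [0, 68]) on line %d",
                 line_no[bad[1L]]), call. = FALSE)
  bad <- which(!df$label %in% c("on", "off", "unknown"))
  if (length(bad))
    stop(sprintf("invalid label on line %d", line_no[bad[1L]]), call. = FALSE)

  ids <- unique(df$patient_id)
  series <- lapply(ids, function(id) {
    rows <- df$patient_id == id
    tt <- t_years[rows]
    if (is.unsorted(tt, strictly = FALSE))
      warning(sprintf("reports for patient %s out of time order; sorting", id),
              call. = FALSE)
    symptom_series(id, tt, score[rows], df$label[rows])
  })
  pd_cohort(series)
}

#' Cohort descriptive statistics
#'
#' @param cohort a [pd_cohort()].
#' @return list with patient/report counts and the mean/SD of per-patient
#'   report counts, mean reporting intervals (days), observation spans
#'   (years) and ages at diagnosis (where present).
#' @export
cohort_descriptives <- function(cohort) {
  stopifnot(inherits(cohort, "pd_cohort"))
  n_rep <- vapply(cohort, function(s) length(s$times), 0L)
  ints <- vapply(cohort, mean_report_interval_days, 0)
  span <- vapply(cohort, function(s) diff(range(s$times)), 0)
  ages <- unlist(lapply(cohort, function(s) s$age_at_diagnosis))
  list(n_patients = length(cohort), n_reports = sum(n_rep),
       reports_mean = mean(n_rep), reports_sd = sd(n_rep),
       interval_mean_days = mean(ints, na.rm = TRUE),
       interval_sd_days = sd(ints[!is.na(ints)]),
       span_mean_years = mean(span), span_sd_years = sd(span),
       age_mean = if (length(ages)) mean(ages) else NA_real_,
       age_sd = if (length(ages) > 1) sd(ages) else NA_real_)
}
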