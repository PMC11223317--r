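#' Point-prevalence numerator indicator
#'
#' Per-record 0/1 indicator for membership in the point-prevalence numerator
#' at a given date. A record counts iff all three hold, every comparison
#' boundary-inclusive:
#' \itemize{
#'   \item \code{start_date <= period_start} (follow-up had begun),
#'   \item \code{end_date >= period_start} (follow-up had not ended),
#'   \item \code{event_date <= period_start} (the event was already recorded).
#' }
#' A missing event date satisfies no inequality, so it yields 0.
#'
#' @param cohort a cohort data.frame (any number of rows).
#' @param period_start the \code{Date} at which prevalence is evaluated.
#' @return integer vector of 0/1, one per record.
#' @export
prevalence_numerator_indicator <- function(cohort, period_start) {
  period_start <- as.Date(period_start)
  as.integer(cohort$start_date <= period_start &
               cohort$end_date >= period_start &
               !is.na(cohort$event_date) &
               cohort$event_date <= period_start)
}

#' Point-prevalence denominator indicator
#'
#' 1 iff the record was under follow-up on the evaluation date:
#' \code{start_date <= period_start} and \code{end_date >= period_start}.
#' The event date is irrelevant, so the numerator conditions are a strict
#' superset and numerator <= denominator always holds.
#'
#' @inheritParams prevalence_numerator_indicator
#' @return integer vector of 0/1, one per record.
#' @export
prevalence_denominator_indicator <- function(cohort, period_start) {
  period_start <- as.Date(period_start)
  as.integer(cohort$start_date <= period_start &
               cohort$end_date >= period_start)
}

#' Point prevalence at a date
#'
#' Proportion of records under follow-up at \code{period_start} whose first
#' event is recorded on or before that date, scaled to \code{multiplier}
#' population. This is lifetime prevalence: there is no lookback limit on the
#' event date. The confidence interval applies Byar's approximation to the
#' numerator count and scales it by \code{multiplier / denominator}.
#'
#' @param cohort a cohort data.frame.
#' @param period_start evaluation date.
#' @param multiplier reporting scale (default per 100,000 population).
#' @param ci_level two-sided confidence level in (0,1).
#' @param label period label carried into the output (defaults to the date).
#' @param period_end optional period end carried into the output for grid
#'   bookkeeping; the estimate itself depends only on \code{period_start}.
#' @return one-row estimate data.frame (see [write_results()] for the layout).
#'   A zero denominator yields \code{NA} estimate and bounds with a warning of
#'   class \code{opencohort_undefined_estimate}, never a division error.
#' @export
point_prevalence <- function(cohort, period_start, multiplier = 100000L,
                             ci_level = 0.95,
                             label = format(as.Date(period_start)),
                             period_end = as.Date(period_start)) {
  period_start <- as.Date(period_start)
  num <- sum(prevalence_numerator_indicator(cohort, period_start))
  den <- sum(prevalence_denominator_indicator(cohort, period_start))
  period <- list(period_start = period_start, period_end = as.Date(period_end),
                 label = label)
  if (den == 0L) {
    warn_undefined("point_prevalence", label)
    est <- lo <- hi <- NA_real_
  } else {
    ci <- byar_interval(num, ci_level)
    sc <- scale_interval(ci, denominator = den, multiplier = multiplier)
    est <- sc[["estimate"]]; lo <- sc[["lower"]]; hi <- sc[["upper"]]
  }
  new_estimate_row("point_prevalence", period, num,
                   denominator_count = as.integer(den),
                   person_days = NA_integer_, person_years = NA_real_,
                   estimate = est, ci_lower = lo, ci_upper = hi,
                   multiplier = multiplier, ci_level = ci_level)
}
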