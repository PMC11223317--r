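#' Period-incidence numerator indicator
#'
#' 1 iff the record's first event is new within the half-open period and the
#' record's follow-up overlaps it:
#' \itemize{
#'   \item \code{period_start <= event_date < period_end} (inclusive at the
#'     period start, strictly before the period end),
#'   \item \code{end_date >= period_start},
#'   \item \code{start_date < period_end}.
#' }
#' A missing event date yields 0. Note the conditions do not require
#' \code{event_date <= end_date}: an event dated after follow-up end but
#' inside the period still counts, while the record's person-time is censored
#' at \code{end_date}. [validate_cohort()] flags such records.
#'
#' @param cohort a cohort data.frame.
#' @param period a list or one-row data.frame with \code{period_start} and
#'   \code{period_end} dates (half-open \code{[period_start, period_end)}).
#' @return integer vector of 0/1, one per record.
#' @export
incidence_numerator_indicator <- function(cohort, period) {
  ps <- as.Date(period$period_start)
  pe <- as.Date(period$period_end)
  ev <- cohort$event_date
  as.integer(!is.na(ev) & ev >= ps & ev < pe &
               cohort$end_date >= ps &
               cohort$start_date < pe)
}

#' Person-time contributed to a period, in whole days
#'
#' The at-risk window is \code{[max(start_date, period_start),
#' min(end_date, event_date, period_end))}, with a missing event date
#' non-binding inside the minimum, provided all eligibility conditions hold:
#' \itemize{
#'   \item \code{start_date < period_end},
#'   \item \code{end_date >= period_start},
#'   \item \code{event_date >= period_start} or missing (no prior event),
#'   \item \code{event_date > start_date} or missing (at risk after entry).
#' }
#' Otherwise, or when the window is degenerate, the contribution is 0 days.
#' Day counts are exact integers; divide by 365.25 for person-years (or use
#' [person_time()]).
#'
#' @inheritParams incidence_numerator_indicator
#' @return integer vector of day counts, one per record.
#' @export
person_time_days <- function(cohort, period) {
  ps <- as.Date(period$period_start)
  pe <- as.Date(period$period_end)
  ev <- cohort$event_date
  eligible <- cohort$start_date < pe &
    cohort$end_date >= ps &
    (is.na(ev) | ev >= ps) &
    (is.na(ev) | ev > cohort$start_date)
  start_obs <- pmax(cohort$start_date, ps)
  end_obs <- pmin(cohort$end_date, pe)
  has_ev <- !is.na(ev)
  end_obs[has_ev] <- pmin(end_obs[has_ev], ev[has_ev])
  days <- pmax(0L, as.integer(end_obs - start_obs))
  days[!eligible] <- 0L
  days
}

#' Person-time contributed to a period, in person-years
#'
#' [person_time_days()] divided by 365.25 once per record. The divisor is the
#' fixed mean Julian-year length, not configurable.
#'
#' @inheritParams incidence_numerator_indicator
#' @return numeric vector of person-years, one per record.
#' @export
person_time <- function(cohort, period) {
  person_time_days(cohort, period) / 365.25
}

#' Period incidence rate
#'
#' New first events per person-year within a half-open calendar period, scaled
#' to \code{multiplier} person-years. The numerator sums
#' [incidence_numerator_indicator()]; the denominator accumulates exact
#' integer at-risk days over records and divides by 365.25. The confidence
#' interval applies Byar's approximation to the event count and scales it by
#' \code{multiplier / person_years}.
#'
#' @param cohort a cohort data.frame.
#' @param period a list or one-row data.frame with \code{period_start},
#'   \code{period_end} and optionally \code{label}.
#' @param multiplier reporting scale (default per 100,000 person-years).
#' @param ci_level two-sided confidence level in (0,1).
#' @return one-row estimate data.frame. Zero person-time yields \code{NA}
#'   estimate and bounds with a warning of class
#'   \code{opencohort_undefined_estimate}.
#' @export
period_incidence <- function(cohort, period, multiplier = 100000L,
                             ci_level = 0.95) {
  if (is.null(period$label)) period$label <- format(as.Date(period$period_start))
  num <- sum(incidence_numerator_indicator(cohort, period))
  days <- sum(person_time_days(cohort, period))
  py <- days / 365.25
  if (py == 0) {
    warn_undefined("incidence", period$label)
    est <- lo <- hi <- NA_real_
  } else {
    ci <- byar_interval(num, ci_level)
    sc <- scale_interval(ci, denominator = py, multiplier = multiplier)
    est <- sc[["estimate"]]; lo <- sc[["lower"]]; hi <- sc[["upper"]]
  }
  new_estimate_row("incidence",
                   list(period_start = as.Date(period$period_start),
                        period_end = as.Date(period$period_end),
                        label = period$label),
                   num, denominator_count = NA_integer_,
                   person_days = as.integer(days), person_years = py,
                   estimate = est, ci_lower = lo, ci_upper = hi,
                   multiplier = multiplier, ci_level = ci_level)
}
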