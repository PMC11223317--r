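METRICS <- c("incidence", "point_prevalence", "period_prevalence")
FREQUENCIES <- c(annual = "year", quarterly = "3 months", monthly = "month")

#' Analysis configuration for a time-series run
#'
#' @param start_year,end_year first and last calendar year of the study
#'   window (inclusive); \code{start_year <= end_year}.
#' @param frequency one of \code{"annual"}, \code{"quarterly"},
#'   \code{"monthly"}.
#' @param metrics non-empty subset of \code{"incidence"},
#'   \code{"point_prevalence"}, \code{"period_prevalence"}.
#' @param multiplier positive reporting scale, default 100,000.
#' @param ci_level two-sided confidence level, default 0.95.
#' @param stratifiers character vector of stratifier column names to subgroup
#'   by (each analysed separately, in addition to the overall series).
#' @return an \code{analysis_config} list.
#' @export
analysis_config <- function(start_year, end_year, frequency = "annual",
                            metrics = c("incidence", "point_prevalence"),
                            multiplier = 100000L, ci_level = 0.95,
                            stratifiers = character()) {
  start_year <- as.integer(start_year); end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || start_year > end_year)
    stop("start_year must be <= end_year")
  frequency <- match.arg(frequency, names(FREQUENCIES))
  metrics <- match.arg(metrics, METRICS, several.ok = TRUE)
  if (length(metrics) == 0L) stop("metrics must be non-empty")
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("multiplier must be positive")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0,1)")
  structure(list(start_year = start_year, end_year = end_year,
                 frequency = frequency, metrics = metrics,
                 multiplier = as.integer(multiplier), ci_level = ci_level,
                 stratifiers = as.character(stratifiers)),
            class = "analysis_config")
}

#' Load an analysis configuration from a JSON file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys take the
#' defaults. Values given on the command line override file values.
#'
#' @param path path to a JSON file.
#' @return an \code{analysis_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("start_year", "end_year", "frequency", "metrics", "multiplier",
               "ci_level", "stratifiers")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Build the period grid for a study window
#'
#' One half-open period \code{[period_start, period_end)} per calendar year,
#' quarter or month between January 1 of \code{start_year} and January 1 of
#' \code{end_year + 1}. Each period's end equals the next period's start, so
#' the grid tiles the window exactly: no gaps, no overlaps, and a full-year
#' annual period covers 365 or 366 days.
#'
#' @param config an [analysis_config()], or an integer \code{start_year} if
#'   \code{end_year} is given.
#' @param end_year,frequency used when \code{config} is a bare start year.
#' @return data.frame with \code{period_start}, \code{period_end} (Dates) and
#'   \code{label} (e.g. \code{"2006"}, \code{"2006-Q2"}, \code{"2006-03"}).
#' @export
make_period_grid <- function(config, end_year = NULL, frequency = "annual") {
  if (!inherits(config, "analysis_config")) {
    config <- analysis_config(start_year = config, end_year = end_year,
                              frequency = frequency)
  }
  by <- FREQUENCIES[[config$frequency]]
  starts <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
                as.Date(sprintf("%d-01-01", config$end_year + 1L)),
                by = by)
  ends <- starts[-1L]
  starts <- starts[-length(starts)]
  label <- switch(config$frequency,
    annual = format(starts, "%Y"),
    quarterly = sprintf("%s-Q%d", format(starts, "%Y"),
                        (as.integer(format(starts, "%m")) - 1L) %/% 3L + 1L),
    monthly = format(starts, "%Y-%m"))
  data.frame(period_start = starts, period_end = ends, label = label,
             stringsAsFactors = FALSE)
}

#' Period prevalence over a calendar window
#'
#' An extension metric obtained by rearranging the point-prevalence and
#' incidence rules: the numerator counts records whose event is recorded
#' before the period ends and whose follow-up overlaps the period
#' (\code{event_date < period_end}, \code{end_date >= period_start},
#' \code{start_date < period_end}); the denominator counts records whose
#' follow-up overlaps the period at all (\code{start_date < period_end},
#' \code{end_date >= period_start}) — persons, not person-time. The numerator
#' is always at least the point-prevalence numerator at the same
#' \code{period_start}. This interpretation is the package's own; see the
#' methods vignette.
#'
#' @inheritParams period_incidence
#' @param multiplier reporting scale (default per 100,000 population).
#' @return one-row estimate data.frame.
#' @export
period_prevalence <- function(cohort, period, multiplier = 100000L,
                              ci_level = 0.95) {
  ps <- as.Date(period$period_start)
  pe <- as.Date(period$period_end)
  if (is.null(period$label)) period$label <- format(ps)
  ev <- cohort$event_date
  overlap <- cohort$start_date < pe & cohort$end_date >= ps
  num <- sum(overlap & !is.na(ev) & ev < pe)
  den <- sum(overlap)
  if (den == 0L) {
    warn_undefined("period_prevalence", period$label)
    est <- lo <- hi <- NA_real_
  } else {
    ci <- byar_interval(num, ci_level)
    sc <- scale_interval(ci, denominator = den, multiplier = multiplier)
    est <- sc[["estimate"]]; lo <- sc[["lower"]]; hi <- sc[["upper"]]
  }
  new_estimate_row("period_prevalence",
                   list(period_start = ps, period_end = pe,
                        label = period$label),
                   num, denominator_count = as.integer(den),
                   person_days = NA_integer_, person_years = NA_real_,
                   estimate = est, ci_lower = lo, ci_upper = hi,
                   multiplier = multiplier, ci_level = ci_level)
}

# internal: dispatch one metric on one period for one (sub)cohort
compute_one <- function(metric, cohort, period, multiplier, ci_level) {
  switch(metric,
    incidence = period_incidence(cohort, period, multiplier, ci_level),
    point_prevalence = point_prevalence(cohort, period$period_start,
                                        multiplier, ci_level,
                                        label = period$label,
                                        period_end = period$period_end),
    period_prevalence = period_prevalence(cohort, period, multiplier,
                                          ci_level))
}

#' Compute a stratified incidence/prevalence time series
#'
#' For each period of the grid, each requested metric, and each of (overall +
#' every level of every requested stratifier), computes one estimate row.
#' Point prevalence is evaluated at each period's \code{period_start};
#' incidence and period prevalence over \code{[period_start, period_end)}.
#' Missing stratifier values form an explicit \code{"missing"} category rather
#' than being dropped, and every level observed anywhere in the cohort is
#' emitted for every period even when its numerator and denominator are both
#' zero (the estimate is then \code{NA}). Since each stratifier's levels
#' partition the cohort, stratum numerators and person-day totals sum exactly
#' to the overall row.
#'
#' Periods whose denominator is zero (e.g. grid years before any record
#' enters) produce rows with \code{NA} estimates; one summary warning reports
#' how many.
#'
#' @param cohort a cohort data.frame.
#' @param config an [analysis_config()].
#' @return data.frame of estimate rows, one per period x metric x stratum,
#'   ordered by (metric, stratifier, stratum, period_start). Output is
#'   deterministic and invariant under permutation of the input records.
#' @export
compute_time_series <- function(cohort, config) {
  stopifnot(inherits(config, "analysis_config"))
  avail <- stratifiers(cohort)
  unknown <- setdiff(config$stratifiers, avail)
  if (length(unknown))
    stop("unknown stratifier(s): ", paste(unknown, collapse = ", "),
         if (length(avail)) paste0("; available: ",
                                   paste(avail, collapse = ", "))
         else "; cohort has no stratifier columns")
  grid <- make_period_grid(config)
  n_undefined <- 0L
  run <- function(sub, period, stratifier, stratum) {
    rows <- lapply(config$metrics, function(m) {
      withCallingHandlers(
        compute_one(m, sub, period, config$multiplier, config$ci_level),
        opencohort_undefined_estimate = function(w) {
          n_undefined <<- n_undefined + 1L
          invokeRestart("muffleWarning")
        })
    })
    out <- do.call(rbind, rows)
    out$stratifier <- stratifier
    out$stratum <- stratum
    out
  }
  pieces <- list()
  for (i in seq_len(nrow(grid))) {
    period <- grid[i, ]
    pieces[[length(pieces) + 1L]] <- run(cohort, period, "overall", "overall")
    for (s in config$stratifiers) {
      vals <- cohort[[s]]
      vals[is.na(vals) | vals == ""] <- "missing"
      for (lev in sort(unique(vals))) {
        pieces[[length(pieces) + 1L]] <-
          run(cohort[vals == lev, , drop = FALSE], period, s, lev)
      }
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$metric, out$stratifier, out$stratum, out$period_start), ]
  rownames(out) <- NULL
  if (n_undefined > 0L)
    warning(n_undefined, " estimate(s) undefined (zero denominator), ",
            "emitted as NA")
  out
}
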