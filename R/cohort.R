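#' @keywords internal
"_PACKAGE"

CORE_ROLES <- c("record_id", "start_date", "end_date", "event_date")

#' Construct a cohort table from vectors
#'
#' A cohort is a plain \code{data.frame} (class \code{c("cohort",
#' "data.frame")}) with one row per observation record: an identifier, a
#' follow-up interval \code{[start_date, end_date]}, an optional first-event
#' date, and zero or more categorical stratifier columns. All dates are base
#' \code{Date}s with day granularity; all rule arithmetic is exact day
#' counting.
#'
#' @param record_id vector of opaque identifiers (coerced to character).
#'   Duplicates are allowed: the rules operate per observation row, not per
#'   person.
#' @param start_date,end_date \code{Date} vectors; \code{start_date <=
#'   end_date} is enforced.
#' @param event_date \code{Date} vector, \code{NA} where no first event was
#'   recorded. At most one event per record. An event outside
#'   \code{[start_date, end_date]} is accepted here (see
#'   \code{\link{validate_cohort}}).
#' @param strata optional \code{data.frame} of categorical stratifier columns,
#'   one row per record.
#' @return a cohort \code{data.frame}.
#' @seealso [read_cohort()], [validate_cohort()]
#' @export
cohort <- function(record_id, start_date, end_date, event_date = NULL,
                   strata = NULL) {
  n <- length(start_date)
  if (is.null(event_date)) event_date <- as.Date(rep(NA, n))
  if (is.null(record_id)) record_id <- as.character(seq_len(n))
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  event_date <- as.Date(event_date)
  if (length(end_date) != n || length(event_date) != n)
    stop("start_date, end_date and event_date must have equal length")
  if (anyNA(start_date) || anyNA(end_date))
    stop("start_date and end_date must not be missing")
  bad <- end_date < start_date
  if (any(bad))
    stop(sum(bad), " record(s) with end_date earlier than start_date")
  df <- data.frame(record_id = as.character(record_id),
                   start_date = start_date, end_date = end_date,
                   event_date = event_date, stringsAsFactors = FALSE)
  if (!is.null(strata) && ncol(strata) > 0) {
    if (nrow(strata) != n) stop("strata must have one row per record")
    if (any(names(strata) %in% CORE_ROLES))
      stop("stratifier names may not collide with core columns")
    for (nm in names(strata)) df[[nm]] <- as.character(strata[[nm]])
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Names of the stratifier columns of a cohort
#' @param x a cohort data.frame.
#' @return character vector (possibly empty).
#' @export
stratifiers <- function(x) setdiff(names(x), CORE_ROLES)

#' Read an observation table from CSV
#'
#' Reads a rectangular per-person observation table: one row per record with a
#' follow-up start date, a follow-up end date, an optional first-event date and
#' optional categorical stratifiers. Rows whose end date precedes their start
#' date are rejected (dropped and counted); rows whose event date falls outside
#' the follow-up interval are kept verbatim, with a warning, because the
#' counting rules are defined on the raw dates (use \code{strict = TRUE} to
#' drop them instead).
#'
#' @param path CSV file (RFC-4180, UTF-8, header row mandatory).
#' @param column_map named character vector mapping roles to column names,
#'   e.g. \code{c(start_date = "index_date", end_date = "exit_date",
#'   event_date = "diag_date", ethnicity = "eth")}. Roles
#'   \code{start_date} and \code{end_date} are mandatory; \code{event_date}
#'   and \code{record_id} are optional; every remaining entry names a
#'   stratifier column to carry through (unmapped extra columns are ignored).
#' @param date_format date format string, default ISO-8601
#'   (\code{"\%Y-\%m-\%d"}). Empty cells and the literal \code{"NA"} parse to
#'   a missing event date.
#' @param strict drop (rather than keep-and-warn) records whose event date
#'   falls outside the follow-up interval.
#' @return a cohort \code{data.frame}; attribute \code{"load_report"} holds a
#'   list with \code{n_rows}, \code{n_loaded}, \code{n_rejected},
#'   \code{n_warnings}.
#' @export
read_cohort <- function(path,
                        column_map = c(record_id = "record_id",
                                       start_date = "start_date",
                                       end_date = "end_date",
                                       event_date = "event_date"),
                        date_format = "%Y-%m-%d",
                        strict = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  for (role in c("start_date", "end_date"))
    if (!role %in% names(column_map))
      stop("column_map must map role '", role, "'")
  mapped <- column_map[column_map %in% names(raw) |
                         !names(column_map) %in% CORE_ROLES]
  missing_cols <- setdiff(unname(column_map[intersect(names(column_map),
                                                      CORE_ROLES[2:3])]),
                          names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  strat_roles <- setdiff(names(column_map), CORE_ROLES)
  missing_strat <- setdiff(unname(column_map[strat_roles]), names(raw))
  if (length(missing_strat))
    stop("mapped stratifier column(s) missing: ",
         paste(missing_strat, collapse = ", "))

  n_rows <- nrow(raw)
  parse_date <- function(x, col, allow_na = FALSE) {
    blank <- is.na(x) | x == "" | x == "NA"
    d <- as.Date(rep(NA_character_, length(x)))
    d[!blank] <- as.Date(x[!blank], format = date_format)
    bad <- !blank & is.na(d)
    if (any(bad))
      stop("unparseable date in column '", col, "' at data row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    if (!allow_na && any(blank))
      stop("missing value in mandatory column '", col, "' at data row(s) ",
           paste(utils::head(which(blank), 5L), collapse = ", "))
    d
  }
  if (n_rows == 0L) {
    warning("input file has a header but no data rows: ", path)
    out <- cohort(character(0), as.Date(character(0)), as.Date(character(0)),
                  as.Date(character(0)),
                  strata = stats::setNames(
                    as.data.frame(matrix(character(0), 0, length(strat_roles))),
                    strat_roles))
    attr(out, "load_report") <- list(n_rows = 0L, n_loaded = 0L,
                                     n_rejected = 0L, n_warnings = 1L)
    return(out)
  }
  start <- parse_date(raw[[column_map[["start_date"]]]], column_map[["start_date"]])
  end <- parse_date(raw[[column_map[["end_date"]]]], column_map[["end_date"]])
  event <- if ("event_date" %in% names(column_map) &&
               column_map[["event_date"]] %in% names(raw))
    parse_date(raw[[column_map[["event_date"]]]], column_map[["event_date"]],
               allow_na = TRUE)
  else as.Date(rep(NA, n_rows))
  id <- if ("record_id" %in% names(column_map) &&
            column_map[["record_id"]] %in% names(raw))
    raw[[column_map[["record_id"]]]]
  else as.character(seq_len(n_rows))

  reject <- end < start
  outside <- !is.na(event) & !reject & (event < start | event > end)
  n_warnings <- 0L
  if (any(reject)) {
    warning(sum(reject), " record(s) rejected: end_date precedes start_date ",
            "(data row(s) ", paste(utils::head(which(reject), 5L), collapse = ", "),
            ")")
    n_warnings <- n_warnings + 1L
  }
  if (any(outside)) {
    if (strict) {
      warning(sum(outside), " record(s) dropped (strict mode): event_date ",
              "outside follow-up interval")
      reject <- reject | outside
    } else {
      warning(sum(outside), " record(s) have event_date outside the ",
              "follow-up interval; kept and processed verbatim")
    }
    n_warnings <- n_warnings + 1L
  }
  keep <- !reject
  strata <- if (length(strat_roles))
    stats::setNames(as.data.frame(lapply(strat_roles, function(r)
      raw[[column_map[[r]]]][keep]), optional = TRUE), strat_roles)
  else NULL
  out <- cohort(id[keep], start[keep], end[keep], event[keep], strata = strata)
  attr(out, "load_report") <- list(n_rows = n_rows, n_loaded = sum(keep),
                                   n_rejected = sum(reject),
                                   n_warnings = n_warnings)
  out
}

#' Data-quality report for a cohort
#'
#' Reporting only: counts records whose recorded event date precedes follow-up
#' start, exceeds follow-up end, and records with zero-length follow-up
#' (\code{start_date == end_date}). Such records are legal inputs to the
#' counting rules — an event dated after follow-up end, for instance, can be
#' counted in an incidence numerator while the record's person-time is censored
#' at its end date — so they are surfaced here rather than rejected.
#'
#' @param cohort a cohort data.frame.
#' @return list with counts \code{n_records}, \code{event_before_start},
#'   \code{event_after_end}, \code{zero_length_followup}, and logical
#'   \code{clean}.
#' @export
validate_cohort <- function(cohort) {
  ev <- cohort$event_date
  res <- list(
    n_records = nrow(cohort),
    event_before_start = sum(!is.na(ev) & ev < cohort$start_date),
    event_after_end = sum(!is.na(ev) & ev > cohort$end_date),
    zero_length_followup = sum(cohort$start_date == cohort$end_date))
  res$clean <- res$event_before_start + res$event_after_end +
    res$zero_length_followup == 0L
  class(res) <- "cohort_validation"
  res
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation:", x$n_records, "records\n")
  cat("  event before follow-up start:", x$event_before_start, "\n")
  cat("  event after follow-up end:   ", x$event_after_end, "\n")
  cat("  zero-length follow-up:       ", x$zero_length_followup, "\n")
  invisible(x)
}

#' Write a cohort back to CSV
#'
#' Emits the exact dialect \code{\link{read_cohort}} reads with its default
#' column map: ISO-8601 dates, empty cells for missing event dates, stratifier
#' columns appended after the core four.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (col in c("start_date", "end_date", "event_date"))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        format(df[[col]], "%Y-%m-%d"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}

RESULT_COLUMNS <- c("metric", "period_start", "period_end", "period_label",
                    "stratifier", "stratum", "numerator", "denominator_count",
                    "person_days", "person_years", "estimate", "ci_lower",
                    "ci_upper", "multiplier", "ci_level")

#' Write estimate rows to a long-format CSV
#'
#' One row per metric x period x stratum. Prevalence rows carry a count
#' denominator and empty person-time fields; incidence rows carry person-time
#' and an empty count denominator. Numeric fields are written with 17
#' significant digits so a write/read round trip reproduces them exactly.
#'
#' @param estimates a data.frame of estimate rows as produced by
#'   [point_prevalence()], [period_incidence()], [period_prevalence()] or
#'   [compute_time_series()] (rows may mix metrics).
#' @param path output path.
#' @export
write_results <- function(estimates, path) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    empty <- stats::setNames(
      as.data.frame(matrix(character(0), 0, length(RESULT_COLUMNS))),
      RESULT_COLUMNS)
    utils::write.csv(empty, path, row.names = FALSE, quote = FALSE)
    return(invisible(NULL))
  }
  df <- estimates[order(estimates$metric, estimates$stratifier,
                        estimates$stratum, estimates$period_start), ]
  out <- df[, RESULT_COLUMNS]
  for (col in c("period_start", "period_end"))
    out[[col]] <- format(out[[col]], "%Y-%m-%d")
  for (col in c("person_years", "estimate", "ci_lower", "ci_upper",
                "ci_level"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 17, format = "g"))
  for (col in c("numerator", "denominator_count", "person_days", "multiplier"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a results CSV written by [write_results()]
#' @param path path to a results CSV.
#' @return data.frame with typed columns.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) {
    for (col in RESULT_COLUMNS) df[[col]] <- df[[col]]
    return(df)
  }
  for (col in c("period_start", "period_end"))
    df[[col]] <- as.Date(df[[col]])
  for (col in c("numerator", "denominator_count", "person_days", "multiplier"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  for (col in c("person_years", "estimate", "ci_lower", "ci_upper", "ci_level"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df
}

# internal: one estimate row in the long result layout
new_estimate_row <- function(metric, period, numerator, denominator_count,
                             person_days, person_years, estimate, ci_lower,
                             ci_upper, multiplier, ci_level,
                             stratifier = "overall", stratum = "overall") {
  data.frame(metric = metric,
             period_start = period$period_start,
             period_end = period$period_end,
             period_label = period$label,
             stratifier = stratifier, stratum = stratum,
             numerator = as.integer(numerator),
             denominator_count = denominator_count,
             person_days = person_days,
             person_years = person_years,
             estimate = estimate, ci_lower = ci_lower, ci_upper = ci_upper,
             multiplier = as.integer(multiplier), ci_level = ci_level,
             stringsAsFactors = FALSE)
}

# internal: condition signalled when a denominator is zero
warn_undefined <- function(metric, label) {
  warning(warningCondition(
    paste0(metric, " estimate undefined for period '", label,
           "': zero denominator"),
    class = "opencohort_undefined_estimate"))
}
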