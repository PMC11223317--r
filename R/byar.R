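#' Byar's approximate Poisson confidence interval for a count
#'
#' Cube-root normal approximation to the exact Poisson limits for an observed
#' count O (the APHO/PHE standard form):
#' \deqn{lower = O (1 - 1/(9O) - z/(3\sqrt{O}))^3}
#' \deqn{upper = (O+1) (1 - 1/(9(O+1)) + z/(3\sqrt{O+1}))^3}
#' with z the standard-normal quantile for the chosen two-sided level. The
#' approximation is accurate even at modest counts (within ~1.5% of the exact
#' gamma-quantile limits for counts of 10 or more). For \code{count == 0} the
#' lower bound is 0 by convention and the upper bound follows from the formula
#' with O + 1 = 1.
#'
#' @param count non-negative integer event count(s); vectorised.
#' @param level two-sided confidence level in (0,1); default 0.95.
#' @return data.frame with columns \code{count}, \code{lower}, \code{upper},
#'   \code{level}; one row per count. Deterministic: same inputs give
#'   bit-identical outputs.
#' @examples
#' byar_interval(100)
#' @export
byar_interval <- function(count, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop("level must be a single number strictly between 0 and 1")
  if (any(is.na(count)) || any(count < 0) || any(count != floor(count)))
    stop("count must be a non-negative integer")
  count <- as.integer(count)
  z <- stats::qnorm(1 - (1 - level) / 2)
  o1 <- count + 1
  lower <- ifelse(count == 0L, 0,
                  count * (1 - 1 / (9 * count) - z / (3 * sqrt(count)))^3)
  lower <- pmax(0, lower)
  upper <- o1 * (1 - 1 / (9 * o1) + z / (3 * sqrt(o1)))^3
  data.frame(count = count, lower = lower, upper = upper, level = level)
}

#' Exact Poisson confidence limits via gamma quantiles
#'
#' The exact (Garwood) limits used as the independent oracle for
#' [byar_interval()] in the test-suite; not part of the default output path.
#'
#' @inheritParams byar_interval
#' @return data.frame with \code{count}, \code{lower}, \code{upper},
#'   \code{level}.
#' @export
exact_poisson_interval <- function(count, level = 0.95) {
  alpha <- 1 - level
  count <- as.integer(count)
  lower <- ifelse(count == 0L, 0, stats::qgamma(alpha / 2, count))
  upper <- stats::qgamma(1 - alpha / 2, count + 1)
  data.frame(count = count, lower = lower, upper = upper, level = level)
}

#' Scale a count interval to a reporting scale
#'
#' Divides count, lower and upper by a positive denominator (a person-count
#' for prevalence, person-years for incidence) and multiplies by the reporting
#' multiplier. A positive linear map, so the bound ordering is preserved.
#'
#' @param interval a one-row data.frame from [byar_interval()] (or any list
#'   with \code{count}, \code{lower}, \code{upper}).
#' @param denominator positive real.
#' @param multiplier positive reporting scale, e.g. 100000.
#' @return named numeric vector \code{c(lower, estimate, upper)}.
#' @export
scale_interval <- function(interval, denominator, multiplier = 100000L) {
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      is.na(denominator) || denominator <= 0)
    stop("denominator must be a single positive number")
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    stop("multiplier must be a single positive number")
  f <- multiplier / denominator
  c(lower = interval$lower * f, estimate = interval$count * f,
    upper = interval$upper * f)
}

#' Wilson score interval for a proportion
#'
#' Sensitivity-check alternative to Byar count intervals for prevalence
#' proportions; not used by default anywhere (the default pipeline applies one
#' CI method, Byar on the numerator count, to both metrics).
#'
#' @param numerator non-negative count of successes.
#' @param denominator positive count of trials.
#' @param level two-sided confidence level in (0,1).
#' @return named numeric vector \code{c(lower, estimate, upper)} on the
#'   proportion scale.
#' @export
wilson_interval <- function(numerator, denominator, level = 0.95) {
  if (denominator <= 0) stop("denominator must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- numerator / denominator
  n <- denominator
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), estimate = p, upper = min(1, centre + half))
}
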