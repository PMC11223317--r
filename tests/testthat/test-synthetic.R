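test_that("synthetic_cohort_spec validates its parameters", {
  expect_error(synthetic_cohort_spec(0, "2006-01-01", "2010-01-01",
                                     hazard = 0.1), "positive integer")
  expect_error(synthetic_cohort_spec(10, "2010-01-01", "2006-01-01",
                                     hazard = 0.1), "window_start")
  expect_error(synthetic_cohort_spec(10, "2006-01-01", "2010-01-01",
                                     hazard = -1), "hazard")
  expect_error(synthetic_cohort_spec(10, "2006-01-01", "2010-01-01",
                                     hazard = 0.1,
                                     followup = list(type = "fixed")),
               "positive 'years'")
  expect_error(synthetic_cohort_spec(
    10, "2006-01-01", "2010-01-01", hazard = 0.1,
    strata = list(s = list(levels = c("a", "b"), weights = c(0.9, 0.2),
                           hazard_multipliers = c(1, 1)))),
    "sum to 1")
})

test_that("generation is deterministic and leaves the RNG alone", {
  spec <- synthetic_cohort_spec(300, "2006-01-01", "2016-01-01",
                                hazard = 0.1, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # a different seed gives a different cohort
  spec2 <- synthetic_cohort_spec(300, "2006-01-01", "2016-01-01",
                                 hazard = 0.1, seed = 100)
  expect_false(identical(a, generate_cohort(spec2)))
  # generation must not disturb the caller's RNG stream
  set.seed(123); ref <- runif(2)
  set.seed(123); first <- runif(1)
  invisible(generate_cohort(spec))
  expect_identical(c(first, runif(1)), ref)
})

test_that("generated cohorts respect the stated world", {
  spec <- synthetic_cohort_spec(
    2000, "2006-01-01", "2016-01-01", entry = "uniform",
    followup = list(type = "exponential", mean_years = 3), hazard = 0.15,
    seed = 7,
    strata = list(eth = list(levels = c("a", "b"), weights = c(0.7, 0.3),
                             hazard_multipliers = c(1, 3))))
  ch <- generate_cohort(spec)
  expect_equal(nrow(ch), 2000L)
  expect_true(all(ch$start_date >= spec$window_start))
  expect_true(all(ch$end_date <= spec$window_end))
  expect_true(all(ch$end_date > ch$start_date))
  ev <- ch$event_date[!is.na(ch$event_date)]
  expect_true(all(ev > ch$start_date[!is.na(ch$event_date)]))
  expect_true(all(ev <= ch$end_date[!is.na(ch$event_date)]))
  expect_true(validate_cohort(ch)$clean)
  expect_setequal(unique(ch$eth), c("a", "b"))
  # higher-hazard stratum has the higher crude event fraction
  frac <- tapply(!is.na(ch$event_date), ch$eth, mean)
  expect_gt(frac[["b"]], frac[["a"]])
})

test_that("near-zero hazard yields an all-missing event column", {
  ch <- generate_cohort(synthetic_cohort_spec(
    1000, "2006-01-01", "2010-01-01", hazard = 1e-9, seed = 8))
  expect_true(all(is.na(ch$event_date)))
})

test_that("event counts match the closed-form expectation", {
  # fixed 1-year follow-up at hazard 0.2/py: P(event) = 1 - exp(-0.2)
  spec <- synthetic_cohort_spec(1000, "2006-01-01", "2010-01-01",
                                entry = "window_start",
                                followup = list(type = "fixed", years = 1),
                                hazard = 0.2, seed = 9)
  ch <- generate_cohort(spec)
  p <- 1 - exp(-0.2)
  expected <- 1000 * p
  tol <- 3 * sqrt(1000 * p * (1 - p))
  expect_lt(abs(sum(!is.na(ch$event_date)) - expected), tol)
})

test_that("expected_point_prevalence covers the supported shapes only", {
  spec <- synthetic_cohort_spec(100, "2000-01-01", "2030-01-01",
                                entry = "window_start",
                                followup = list(type = "fixed", years = 25),
                                hazard = 0.1)
  ten_years <- as.Date("2000-01-01") + round(10 * 365.25)
  t_grid <- as.integer(ten_years - as.Date("2000-01-01")) / 365.25
  expect_equal(expected_point_prevalence(spec, ten_years),
               1 - exp(-0.1 * t_grid), tolerance = 1e-12)
  # the day grid cannot hit 10 x 365.25 days exactly; closed form within 1e-3
  expect_equal(expected_point_prevalence(spec, ten_years), 1 - exp(-1),
               tolerance = 1e-3)
  expect_equal(expected_point_prevalence(spec, "2000-01-01"), 0)
  # stratified closed form is the mixture over multipliers
  specs <- synthetic_cohort_spec(
    100, "2000-01-01", "2030-01-01", entry = "window_start",
    followup = list(type = "fixed", years = 25), hazard = 0.1,
    strata = list(g = list(levels = c("lo", "hi"), weights = c(0.6, 0.4),
                           hazard_multipliers = c(0.5, 2))))
  expect_equal(expected_point_prevalence(specs, ten_years),
               0.6 * (1 - exp(-0.05 * t_grid)) + 0.4 * (1 - exp(-0.2 * t_grid)),
               tolerance = 1e-12)
  # unsupported shapes are refused, not approximated
  uni <- synthetic_cohort_spec(100, "2000-01-01", "2030-01-01",
                               entry = "uniform",
                               followup = list(type = "fixed", years = 25),
                               hazard = 0.1)
  expect_error(expected_point_prevalence(uni, ten_years), "unsupported")
  short <- synthetic_cohort_spec(100, "2000-01-01", "2030-01-01",
                                 entry = "window_start",
                                 followup = list(type = "fixed", years = 2),
                                 hazard = 0.1)
  expect_error(expected_point_prevalence(short, ten_years), "unsupported")
})

test_that("oracle_person_time equals the day-count rule on known cases", {
  p <- per("2006-01-01", "2007-01-01")
  expect_equal(oracle_person_time(rec("2005-01-01", "2010-01-01"), p), 365L)
  expect_equal(oracle_person_time(rec("2007-01-01", "2010-01-01",
                                      "2008-01-01"), p), 0L)  # Z_d false
  expect_equal(oracle_person_time(rec("2005-01-01", "2010-01-01",
                                      "2006-07-01"), p), 181L)
  expect_equal(oracle_person_time(rec("2007-06-01", "2010-01-01"),
                                  per("2008-01-01", "2009-01-01")), 366L)
})

test_that("oracle_counts agrees with the rule modules on random cohorts", {
  ch <- random_raw_cohort(300, seed = 61)
  for (p in random_periods(5, seed = 62)) {
    oc <- oracle_counts(ch, p)
    expect_equal(unname(oc["prev_numerator"]),
                 sum(prevalence_numerator_indicator(ch, p$period_start)))
    expect_equal(unname(oc["prev_denominator"]),
                 sum(prevalence_denominator_indicator(ch, p$period_start)))
    expect_equal(unname(oc["inc_numerator"]),
                 sum(incidence_numerator_indicator(ch, p)))
  }
  # degenerate cases
  empty <- cohort(character(0), as.Date(character(0)), as.Date(character(0)))
  expect_equal(unname(oracle_counts(empty, per("2006-01-01", "2007-01-01"))),
               c(0L, 0L, 0L))
  one <- rec("2004-01-01", "2010-01-01", "2005-01-01")
  expect_equal(unname(oracle_counts(one, per("2006-01-01", "2007-01-01"))),
               c(1L, 1L, 0L))
})
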