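# one-record cohort with convenient date literals
rec <- function(start, end, event = NA, id = "r1") {
  cohort(id, as.Date(start), as.Date(end), as.Date(event))
}

# half-open analysis period
per <- function(start, end, label = as.character(start)) {
  list(period_start = as.Date(start), period_end = as.Date(end),
       label = label)
}

# raw random records, deliberately including events outside follow-up and
# zero-length follow-up, so the rules are exercised verbatim (unlike the
# well-behaved synthetic generator)
random_raw_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    origin <- as.Date("2000-01-01")
    start <- origin + sample.int(7000L, n, replace = TRUE)
    end <- start + sample.int(4000L, n, replace = TRUE) - 1L
    event <- origin + sample.int(11000L, n, replace = TRUE)
    event[stats::runif(n) < 0.4] <- NA
    cohort(seq_len(n), start, end, event)
  })
}

random_periods <- function(k, seed, min_days = 30L, max_days = 730L) {
  withr::with_seed(seed, {
    origin <- as.Date("2000-01-01")
    lapply(seq_len(k), function(i) {
      ps <- origin + sample.int(8000L, 1L)
      per(ps, ps + sample(seq.int(min_days, max_days), 1L))
    })
  })
}

write_temp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
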