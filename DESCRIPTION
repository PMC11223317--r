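Package: opencohort
Title: Incidence and Prevalence Time Series for Open Cohorts
Version: 0.1.0
Authors@R:
    person("Open Cohort Analytics Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Automated calculation of point-prevalence and period-incidence
    time series from open-cohort observation tables, where individuals enter
    and exit follow-up at arbitrary calendar dates. Implements explicit
    per-record inclusion rules and exact day-count person-time denominators
    (divided by 365.25 to give person-years), Byar's approximation to Poisson
    confidence intervals, subgroup stratification, a synthetic open-cohort
    generator with known ground truth, and brute-force oracles so every rule
    is verifiable without access to any licensed dataset. Includes a command
    line interface for batch computation on CSV extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
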