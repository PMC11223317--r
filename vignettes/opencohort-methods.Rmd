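---
title: "Methods: rule-based incidence and prevalence in open cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based incidence and prevalence in open cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opencohort)
```

## The problem

Open cohorts — registries and electronic-health-record extractions where
individuals enter and leave follow-up on their own calendar schedules —
make even "simple" descriptive epidemiology fiddly: every estimate needs a
person-level decision about who is under observation when, and small
differences in boundary conventions (is a person who exits on 1 January
still in the denominator that day?) silently change published rates. This
package fixes one explicit, testable ruleset and automates it into
stratified time series.

Each record is a follow-up interval `[start_date, end_date]` with an
optional first-event date. Records are rows, not people: a person
re-extracted under two identifiers is two rows, and the rules are applied
per row. The first recorded event is the only event; recurrent events,
competing risks and standardisation are out of scope.

## The estimators

**Point prevalence** at a date \(t\) is a binomial proportion: among records
with \(\text{start} \le t \le \text{end}\) (the denominator), the fraction
with a recorded event date \(\le t\). Every comparison is inclusive, so a
person whose follow-up ends exactly on \(t\), or whose event is recorded
exactly on \(t\), counts. This is *lifetime* prevalence — there is no
lookback window; a period-limited variant is deliberately not implemented
because no convention for it was fixed.

**Period incidence** over a half-open period \([p_0, p_1)\) is a rate: the
number of first events with \(p_0 \le \text{event} < p_1\) (from records
whose follow-up overlaps the period) divided by the person-time at risk,

\[
\mathrm{PT} = \sum_r \frac{\big(\min(\text{end}_r, \text{event}_r, p_1) -
  \max(\text{start}_r, p_0)\big)_+}{365.25},
\]

where a record contributes only if \(\text{start}_r < p_1\),
\(\text{end}_r \ge p_0\), and its event (if any) is neither before \(p_0\)
nor on/before its own entry day. A missing event date is non-binding inside
the minimum. Day counts are exact integers, divided by 365.25 once per
record; the divisor is the mean Julian year and is not configurable, so
person-years are comparable across runs and tools.

**Period prevalence** is shipped as a clearly-labelled extension: the
denominator uses the incidence-style overlap conditions (persons, not
person-time), the numerator counts records with an event before the period
ends and follow-up overlapping the period. The source description of this
rearrangement is ambiguous; the implementation here is one documented
reading, and its only asserted relationship to the other metrics is the
set-inclusion property (its numerator dominates the point-prevalence
numerator at the period start), which the tests check by brute force.

### Boundary conventions

The half-open period does the bookkeeping: annual periods
`[Jan 1, next Jan 1)` abut exactly, an event on 31 December belongs to the
closing year, an event on 1 January to the opening one, and person-days sum
without gap or double count across any partition of a window. Point
prevalence is anchored at each period's start date (1 January for annual
series); the anchor is a convention — the start date is the only date the
prevalence rules reference.

### Pathological records

The rules are applied verbatim to records whose event date falls outside
their follow-up interval (such rows can arise upstream of any analysis
tool). Verbatim application has two consequences the package surfaces
rather than hides: such an event can be counted in an incidence numerator
while the record contributes no (or censored) person-time; and the
incidence *numerator* loses exact additivity over period splits (the
overlap conditions reference follow-up, not the event, so a split can
reassign the event to a sub-period whose overlap test fails). Person-time
is additive for arbitrary records — its eligibility conditions only exclude
windows that are empty anyway. `validate_cohort()` counts these records,
`read_cohort(strict = TRUE)` drops them, and the additivity tests use clean
cohorts for the numerator and arbitrary ones for person-time.

## Confidence intervals

Both metrics use Byar's cube-root normal approximation to the exact Poisson
limits of the numerator count \(O\), scaled by multiplier/denominator:

\[
O\Big(1 - \tfrac{1}{9O} - \tfrac{z}{3\sqrt{O}}\Big)^3
\quad\text{and}\quad
(O{+}1)\Big(1 - \tfrac{1}{9(O+1)} + \tfrac{z}{3\sqrt{O+1}}\Big)^3 .
\]

\(z\) is computed from `qnorm`, so the level is configurable; for
\(O = 0\) the lower bound is 0 by convention. Applying a Poisson interval
to a prevalence *proportion* is a modelling choice inherited from the
ruleset being implemented (one CI method for all outputs); it is accurate
when prevalence is small relative to the denominator, and
`wilson_interval()` is exposed for sensitivity checks when it is not.
`exact_poisson_interval()` (gamma quantiles) exists purely as the test
oracle: the suite requires Byar within 1.5% of it for counts ≥ 10 and
94–96% empirical coverage at a Poisson mean of 50.

A zero denominator (a grid year before any record enters) yields an
explicitly `NA` estimate with a classed warning, never an error or a fake
zero, so full-window grids remain emittable.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `multiplier` | persons or person-years | 100,000 | the field's customary reporting scale |
| `ci_level` | probability | 0.95 | convention; any level in (0,1) works |
| `frequency` | — | annual | annual Jan-1-anchored series; quarterly/monthly for finer grids |
| person-year divisor | days | 365.25 (fixed) | definitional, not tunable |
| `strict` | flag | off | drop rather than keep-and-warn event-outside-follow-up rows |

Stratified runs partition by each requested stratifier separately; missing
stratum labels become an explicit `"missing"` category (subgroup reporting
conventionally includes it), and every level is emitted for every period
even when empty.

## The synthetic world

`generate_cohort()` emulates exactly the structure the rules need and
nothing more: entry uniform over the window (or everyone on day one), exit
after fixed or exponential follow-up truncated at the window end (at least
one day), and a single latent exponential time to first event at a constant
per-stratum hazard. Continuous event times are floored to whole days; a
same-day tie with entry is nudged to the next day so the strict
event-after-entry rule is satisfiable by construction, and events past exit
are recorded as missing. Generated cohorts therefore never contain
pathological records — which is why the *verbatim-rule* pathologies above
are tested with a separate raw-record generator instead.

Default scenario parameters used across the tests (hazards of 0.02–0.2 per
person-year, follow-up means of 2–5 years, windows of 5–16 years, cohorts
of 400–20,000) are the magnitudes a primary-care chronic-condition series
would show; they are stated once and not tuned.

What a green test does establish: the implementation counts and accumulates
exactly as the rules specify, the CIs are calibrated for the Poisson regime,
and the pooled estimator recovers a known constant hazard. What it does not:
anything about real EHR data — coding drift, recording improving over time,
duplicate patients, denominators that should be narrower than the whole
cohort. Those are analyst judgements, not rule properties.

Closed-form checks live on a day grid, so "10 years after entry" is 3,652
whole days, not 10 × 365.25; the expectations are computed on the same grid
and the tests compare against the grid value exactly and the continuous
value within 1e-3.

## Numerical and design choices

- All dates are base `Date`s; differences are exact day counts. No
  datetimes, no time zones.
- Person-days are accumulated as integers and divided once; stratified
  person-day totals therefore partition exactly, and the partition tests
  assert integer identity rather than float closeness.
- The generator draws from one seeded stream in record order
  (`withr::with_seed`), leaving the caller's RNG untouched; cohorts,
  result tables and CLI outputs are byte-identical across reruns.
- Results CSVs write numerics with 17 significant digits so write→read is
  an identity; cohort CSVs are the same dialect the reader accepts.
- Config files are JSON (`read_config()`); command-line flags override
  file values, which override built-in defaults.
- CLI exit codes: 0 success, 1 data errors, 2 usage errors; logs to stderr,
  results only to `--output`.

## Known limitations

- One event per record; no recurrent events, competing risks, or
  age/sex standardisation.
- Lifetime prevalence only; no lookback-limited prevalence.
- The period-prevalence definition is an interpretation (above), not a
  canonical one.
- Byar-on-proportions degrades as prevalence approaches the denominator
  scale; use the Wilson alternative to check.
- The synthetic generator is a test instrument, not a realistic patient
  simulator.
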