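---
title: "A needs-based workforce simulation model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A needs-based workforce simulation model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrhsim)
```

`hrhsim` projects the supply of and requirement for a health profession's
full-time-equivalent (FTE) capacity in a regional public health system, one
year at a time, and rehearses policy options as parameter overrides. This
vignette records the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic test machinery does and does not
establish.

## The model

**Supply.** The state is the headcount of licensed providers by single year
of age. Each annual step applies, in a fixed order: (1) exits — age `x`
loses fraction `e(x)` of its headcount; (2) aging — survivors move to age
`x + 1`, with the configured top age absorbing (mass at `max_age` stays
there rather than leaving the system, and is thinned only by the exit rate
at that age); (3) entries — the year's graduates routed to this stock, plus
in-migrants, enter at the entrant age distribution (default: a point mass
at age 23). The order "exits before aging before entries" is a modelling
convention; the source data constrain only annual totals, and any fixed
order preserves the conservation identity
`total(t+1) = total(t) - exits + entrants + in-migrants` exactly, which the
test suite asserts to machine precision. Age matters because exit rates may
rise with age: of two stocks with equal totals, the one with more mass at
high-exit ages shrinks faster, and `adjust_exit_schedule()` scales rates
above an age cut-off to rehearse retirement policies.

**Training.** In-training cohorts are indexed by years remaining to
graduation. Intake enters at the full programme length; each advance moves
every cohort one year closer; the cohort reaching zero graduates. The
programme's *total* attrition is applied once, as a survival factor at
graduation, rather than spread per-year: only the total rate is observed,
and applying it at graduation makes the cohort arithmetic exact — 85 seats
at 18% attrition give 69.7 ≈ 70 graduates, the relation the source records
report. (The data source's table states the attrition as 19%, its narrative
as "roughly 18%"; the fixture defaults to 0.18 because that value
reproduces the printed 70-graduate flow, and the 0.19 variant remains
configurable.) Fractional students are carried exactly through the
pipeline; rounding is confined to the reporting layer. A seat change at
year `t` cannot alter graduate flow before `t + L` (`L` = programme
length) — the lag that makes enrolment increases a slow lever — and the
engine reproduces this bit-exactly: a seat-doubling scenario's supply
columns are `identical()` to baseline for the first `L` simulated years.

**Work and productivity.** FTE supply = headcount × participation ×
activity. Participation (share of the licensed stock employed in the public
sector) and activity (share of one FTE the average participant works;
values above 1 are overtime "sessions", e.g. 50 h worked against a 40 h
nominal week = 1.25) are aggregate scalars, not age-varying — only
aggregate values are observed. Both input paths occurring in source data
are supported: a rate directly, or an employed headcount from which the
rate is derived (30 employed of 55 licensed → 0.5455). The trajectory also
reports a *no-sessions* column (activity forced to 1), the capacity the
employed stock could deliver without overtime. Overtime is known to risk
depressing productivity and raising exits, but no functional form is
observed, so no feedback is modelled: the engine only warns when a scenario
pushes activity past a configurable cap (default 1.5).

**Needs.** Required services = population × per-capita condition rate ×
planned items per affected person per year, summed over conditions and
strata, times the public-sector share; required FTE divides by productivity
(items per FTE per year). Three deliberate simplifications: incidence and
prevalence are both treated as point-in-time per-capita annual rates (the
sources mix the two labels); comorbidity is ignored — condition
contributions add independently, consistent with the multiply-and-sum
structure of the needs model; and population growth is uniform across
strata (no age-specific fertility or mortality is available), so a single
degenerate "all ages/sexes" stratum behaves identically to a stratified
table, which the engine permits. The share is applied exactly once, in
`required_services()`; `required_fte()` never reapplies it.

## The Jamaica baseline and its two calibrations

The packaged fixture (`jamaica_baseline()`) encodes the 2008 SERHA
pharmacist baseline: 85 seats, 4-year programme, 18% attrition, 90%
graduate out-migration, no in-migration, 55 licensed providers (mean age
36), flat 5%/yr exits, 30 employed at 125% activity, productivity 16,800
items/FTE/yr, population 1.33 million, public-sector share 30%, 15-year
horizon. Two quantities are not directly observed and are calibrated:

1. **The needs table.** Only range endpoints are recorded: rates from 0.1%
   (tuberculosis, rheumatic fever) to 0.9% (cancer) among the named
   low-prevalence conditions, and levels of service from 3 (arthritis) to
   10 (psychosis) items/person/yr. `jamaica_condition_table()` fills in the
   named chronic and infectious conditions with plausible placeholder
   rates, and `calibrate_to_baseline()` rescales all rates uniformly so the
   year-0 requirement equals 150 FTE (2,520,000 items at 16,800 per FTE).
   Because the requirement is linear in the rates the rescaling is exact,
   and doubling the target doubles every rate-level product. The emitted
   file is named `needs_synthetic.csv` and its rates are calibration
   artifacts, not estimates; levels of service keep their observed values.
   (On the rate endpoints, one source table prints "0.01%" for
   tuberculosis/rheumatic fever where the narrative prints 0.1%; the
   fixture follows the narrative value.)
2. **Population growth.** No regional growth rate is recorded, but the
   baseline shortage is described as growing from 110 to about 150 FTE over
   15 years. The final-year gap is continuous and strictly increasing in
   the growth rate (requirements scale with population, supply does not),
   so `calibrate_growth()` recovers the unique rate in a bounded interval
   by root-finding (`stats::uniroot`, interval [-0.05, 0.10], achieved-gap
   tolerance 0.01 FTE). The result, 2.536%/yr, is stored with the fixture
   as a documented calibration artifact — it is what makes the baseline
   curve end at 150 FTE, not an observed vital rate, and it is noticeably
   higher than recent Caribbean population growth; it absorbs everything
   the model omits (population aging into higher-need groups, service
   expansion) into a single growth term.

## Graduate routing: two interpretations, never mixed

The observed facts — 90% of graduates do not enter the regional workforce,
and 5–10% of graduates enter the public service — admit two readings of
where inflow lands, and the engine implements both behind an explicit
switch (`supply$entry_mode`):

- `"regional"` (baseline): graduates net of out-migration join the regional
  *licensed* stock; participation is applied uniformly every year to obtain
  the employed sub-stock. This is the reading consistent with the stock
  arithmetic of the baseline (6.97 entrants/yr against 5% exits on 55).
- `"public_direct"` (retention scenarios): the tracked stock *is* the
  public-sector employed sub-stock (initialised at the employed headcount,
  30), and `public_entry_fraction` of each year's graduates enters it
  directly. The 25%-retention scenario is expressed this way because the
  lever is "fraction of graduates retained by the public sector", which is
  a statement about entry to employment, not to licensure.

A run uses exactly one mode; scenario files set it explicitly, and year-0
FTE supply is identical under both (30 × 1.25 = 37.5), so scenario
trajectories remain comparable at their shared origin. The `headcount`
column reports whichever stock is being tracked.

## Scenarios and reporting

Overrides are dotted-path rules: `set` (step value holding from its start
year), `scale` (multiple of the baseline value), or `grow` (compounding
annual rate applied from the start year). Rates like productivity growth
are resolved per-year and compounded iteratively, so piecewise schedules
compose correctly. The four shipped scenarios are seat-doubling, 25%
public retention, 5%/yr productivity growth, and retention + productivity
combined. Reporting rounding — gaps and required FTE to the nearest ten,
headcounts to integers, items to the nearest hundred — lives only in
`report_rounding()`; simulation state is never rounded.

## Numerical choices and degenerate inputs

- Annual time step throughout; horizon default 15 years, configurable.
- No randomness anywhere in the engine: repeat runs are bit-identical, and
  the CLI accepts `--seed` only for interface uniformity.
- The initial age placement of a stock known only by total and mean age is
  a discretized decreasing triangle over ages 23–62 (weights
  `max_age - age + 1`), whose discrete mean is exactly 36; under a flat
  exit rate the projected totals are independent of this placement, which
  the closed-form oracle check exploits.
- Degenerate inputs are legal where they are meaningful: empty populations
  yield zero requirement, zero-seat pipelines drain to zero graduates in
  one programme length, a flat exit rate of 1 empties the stock in a year,
  and a horizon of 0 returns only the initial state. Invalid inputs
  (rates outside [0, 1], non-positive productivity, growth at or below
  -100%/yr, mismatched strata) are rejected, and configuration validation
  reports *every* violation, not just the first.
- Ties among overrides applicable in the same year resolve to the latest
  start year, then to listing order.

## What the synthetic machinery shows — and does not

`generate_random_case()` draws schema-valid configurations (uniform
parameters within type bounds, Mersenne–Twister under a locally-scoped
seed, so fixtures regenerate identically across platforms). The property
suite uses it to check conservation, linearity and monotonicity of the
requirement, oracle equivalence of the cohort projection (1,000 randomized
flat-exit cases against the geometric series at 10⁻⁹ relative), scenario
monotonicity in each policy lever, determinism, and config round-trip
stability. Test problem sizes — tables of up to 5 conditions and 4 strata,
horizons up to 30 years, 100–1,000 random cases per property — keep the
full suite under a minute while exercising every code path; they are
chosen for coverage, not realism.

What passing these tests does *not* show: that the calibrated rates
resemble true condition-specific epidemiology (they are uniform rescalings
of placeholders); that real exit rates are age-flat (the engine supports
age-varying schedules but the fixture has data only for a flat 5%); that
participation and activity are stable over 15 years; or that the
deterministic point trajectories carry their apparent precision — the model
has no uncertainty propagation by design, matching its purpose as a policy
rehearsal tool rather than a forecast.

## Known limitations

Single profession, single region, no inter-regional flows; no feedback from
overtime to productivity or exits; no applicant-pool or admission
modelling; no optimisation over policies; requirements respond to
population growth but not to shifts in the age/sex mix unless the user
supplies stratified tables with their own rates.
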