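---
title: "Economic evaluation of care-delivery models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Economic evaluation of care-delivery models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleroi)
```

# The problem

Rural hospitals that cannot recruit specialist clinicians have three broad
options for an outpatient clinic: send patients to a distant provider
hospital (and subsidise their travel), run a hub-and-spoke telehealth
clinic with a metropolitan partner, or employ the specialist themselves as
a *virtual health practitioner* consulting by videoconference. These
options redistribute both costs (who pays for which staff, who pays for
travel) and income (which site claims activity-based funding for each
attended appointment). teleroi evaluates all three from each site's
perspective with a deterministic cost model, producing per-year cost and
income cells, multi-year net benefit, ROI, breakeven attendance, and
one-way sensitivity sweeps.

The package is organised around a declarative scenario document: staff
lines, site roles, income claims, a travel-subsidy policy, per-year funding
rates and discount schedules are data, not code. The bundled document
(`fracture_clinic_scenario()`) transcribes a three-year consultant-led
orthopedic fracture clinic between a small remote hospital and a tertiary
metropolitan hospital.

# The cost model

**Staffing.** Each staff line costs
`hourly_rate × (1 + on_cost_fraction) × hours_per_clinic` per clinic,
rounded half-up to cents. On-costs are employer wage loadings; the modelled
workplace agreements use exactly 0.23 for medical officers and 0.29 for all
other staff, and a scenario document can restrict lines to a configured set
of on-cost values (`allowed_on_cost_fractions`). A site's per-clinic total
is the exact sum of its (rounded) line costs. Annual staffing cost is
`per-clinic total × clinics held × discount factor`, rounded half-up to
whole dollars at report time.

Staff lines may carry a `line_cost` field holding an externally published
per-clinic cost. The bundled case study uses the published values: four of
its lines differ from the wage formula by one to three cents (e.g. the
radiographer line computes to 261.15 but is published as 261.13). We treat
published line costs as authoritative data with a documented tolerance of
A$0.03 per line (A$0.10 per site total) against the formula, and reject
anything beyond A$0.05 at load time as a probable transcription error.

**Discounting.** Wages and prices are published for the base year
(2016-2017 in the case study) and back-cast to earlier years divisively:
`cost(t) = cost(base) / (1 + r)^k` with r = 2.5%/year. Calibrating k
against the published discounted cost cells shows the source used k = 1
for 2015-2016 everywhere, but k = 3 for 2014-2015 in the staffing
schedules and k = 2 for 2014-2015 in the travel model (regional staffing
and the travel subsidy). No single reading of "2.5% per year" produces
both; rather than silently unify them, both schedules ship in the document
(`staffing`, `travel`) as explicit data, and the inconsistency is surfaced
here. Income is never discounted — only wages and travel prices are.

**Travel subsidy.** `base population × uptake × average cost per claimant ×
discount factor`, with uptake 0.17 and A$1447 per claimant in the case
study. The policy's base population is configurable as all bookings or
attended bookings only. Although a subsidy nominally applies to patients
who attend, the published subsidy cells are arithmetically
`total bookings × 0.17 × 1447` (1136 bookings → 279,445 in 2016-2017), so
the bundled policy uses `all_bookings`; `attended_only` remains available.

# The income model

Income per site per year is `attended × Σ rates of the claimed streams`,
rounded half-up to whole dollars. Attended is `bookings − failed-to-attend
(FTA)`; missed appointments generate no funding. The funding classes
modelled here pay the same rate for new and review appointments, so the
new/review and adult/pediatric splits are carried in the data model but do
not enter the income arithmetic.

**Rate calibration.** Published evaluations print annual income per site
but not the A$-per-appointment rate behind it.
`calibrate_funding_rates()` inverts this: `rate(t) = income(t) /
attended(t)`. The bundled document ships three calibrated streams with
their derivations in comments:

* `provider_telehealth` — from the metropolitan provider site's income
  column (225.04 A$/appointment in 2016-2017); also claimed by the
  virtual-practitioner site, whose published income is identical;
* `recipient_telehealth` — from the rural recipient side (148.22 in
  2016-2017);
* `provider_in_person` — from the regional travel-model provider's income
  column (237.52 in 2016-2017).

The third stream exists because the source's regional provider income
(61,488 / 240,503 / 194,289) is *not* reproducible from the
telehealth-provider rates despite identical attended counts — using the
telehealth rates would give a three-year ROI of 89% for that site against
the published 93%. We follow the published income columns and keep the
discrepancy visible as two distinct provider streams. The calibrated
2014-2015 rates (252.04 provider vs 66.59 recipient) differ sharply from
later years; with no published rate table to check against, they are
treated as data.

# Rounding contract

All reporting uses half-up (commercial) rounding, via `round_half_up()`:
cents for per-clinic line costs, whole dollars for annual cells, one
decimal (or integer) for printed ROI percentages. `base::round()`'s
half-to-even rule is deliberately not used: the published tables round
halves up.

Under this contract, 13 of the 15 published annual cost cells reproduce to
the dollar. The remaining two — the rural telehealth site's 2015-2016 and
2016-2017 staffing cells, published as 140,361 and 143,870 where the
arithmetic gives 140,361.60 and 143,870.64 — cannot be reproduced by *any*
deterministic rounding rule: the same fractional part (.60) is rounded up
elsewhere in the same table (28,089.60 → 28,090; 107,313.60 → 107,314) and
the same row's first-year cell (50,506.63 → 50,507) rounds up. The
package computes 140,362 and 143,871, one dollar high, and the affected
three-year total as 334,740 against the published 334,738; the
corresponding golden checks are intentionally left failing rather than
special-cased. Consequences downstream are nil at printed precision: the
site's ROI is −12.53% either way.

Money is held as doubles rather than a decimal type; magnitudes here
(≤ A$10⁶) are exact in double precision well past cent resolution, and
`round_half_up()` carries a relative-epsilon guard for decimal literals
that are one ulp below their written value.

# Evaluation and breakeven

`run_scenario()` fills every (model, site, year) cost and income cell and
per-position totals. ROI is `100 × (income − cost) / cost`; a site with
zero cost has no defined ROI and reports `NA` (never 0). Net benefit and
ROI always agree in sign, totals are exact sums of the yearly cells, and
ROI is invariant under uniform scaling of cost and income — all
property-tested.

`breakeven_appointments()` returns the smallest whole number of attended
appointments whose income covers the per-clinic cost — a ceiling, because
appointments are indivisible — with a relative epsilon so an exact multiple
is not pushed up a unit. A site with positive cost and no income stream
returns `Inf` ("unreachable"); the travel-model rural site is the case in
point, its per-clinic position being the year's subsidy spread over the
year's clinics. The per-appointment income is the sum of the site's
claimed stream rates in a reference year, defaulting to the scenario's
base year (2016-2017): that is the only year whose calibrated rates
reproduce all three published breakeven counts (6 travel provider, 2
telehealth provider, 12 telehealth rural). For the virtual-practitioner
site the same arithmetic gives 9 appointments (or 6 if it could claim both
telehealth streams); the source's discussion mentions 3, which is not
derivable from any rate the published tables imply, and is deliberately
not reproduced. Published 25%-uptake subsidy cells for 2015-2016 and
2016-2017 (425,234 and 391,146) likewise do not follow from the stated
parameters — linear scaling gives 435,866 and 410,948 — and only the
2014-2015 cell scales as 25/17 of the base case; these cells are excluded
from the golden tests and asserted *divergent* instead. The same applies
to three published sensitivity bounds that disagree with the source's own
linear model by a few hundred dollars (e.g. the 2014-2015 recipient bound
19,369 where `321 × 0.9 × 66.59 = 19,239`).

# Sensitivity analysis

One-way sweeps only, matching the deterministic design: `fta_sweep()`
recomputes income cells over a grid of FTA rates (default {0.10, 0.35}),
holding costs fixed — clinic counts, and therefore staffing costs and the
configured subsidy, do not change with attendance. Attendance under an
override is kept fractional (`bookings × (1 − rate)`), so income is
exactly linear in `1 − rate` before the final dollar rounding; this
reproduces the published interval bounds (e.g. 1136 × 0.9 × 225.04 →
230,080). `uptake_sweep()` is exactly linear in uptake (default grid
{0.17, 0.25}). Probabilistic sensitivity analysis (distributions,
Monte-Carlo) is deliberately out of scope.

# Synthetic activity generator

`generate_activity()` emulates the *structure* of an aggregate activity
report: clinics per year from a Poisson (zero-clinic years rejected),
bookings as a sum of per-clinic Poissons (hence over-dispersed relative to
a single Poisson: variance `λm + λm²`), and binomial FTA, new/review and
adult/pediatric splits. Defaults are set once to the case-study scale — 82
clinics/year, 13.9 bookings/clinic, FTA 0.28, new fraction 0.54, pediatric
0.19 — and every generated table satisfies the activity invariants by
construction. A single integer seed drives one RNG stream (saved and
restored around the call), so output is bit-reproducible.

What it does not emulate: year-on-year trends (the real clinic quadrupled
between its first and second year), correlation between FTA and patient
mix, seasonal structure, or patient-level arrival processes. Passing tests
on synthetic data therefore demonstrate arithmetic and invariant
correctness at realistic scale, not fidelity to any real service's
dynamics.

# Problem sizes and runtime

Everything is desk-scale: the case study is 3 years × ≤5 staff lines ×
3 models, and the property suites use 10⁴ random breakeven pairs, 20–25
random calibration/cost scenarios and 40–60 generated years. The full test
suite runs in seconds on one CPU.

# Known limitations

* The model covers human resources, travel subsidy and activity-based
  funding only — no capital, equipment, videoconferencing infrastructure or
  overheads, and no discounting of income streams.
* Findings from the bundled case study are specific to one high-volume
  orthopedic clinic under Queensland funding arrangements; the
  configuration schema is general but conclusions do not transfer without
  re-parameterisation.
* Telehealth substitution rates (what fraction of in-person care a
  videoconference clinic can actually replace) are outside the model.
* Activity is aggregate per year; there are no patient-level records, so
  case-mix effects on funding are invisible.
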