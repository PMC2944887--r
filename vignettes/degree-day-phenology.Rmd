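---
title: "Growing degree-days and phenological advancement: methods"
author: "phenogdd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing degree-days and phenological advancement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogdd)
```

## The scientific problem

Ectotherm development is paced by accumulated heat, not by the calendar.
For univoltine, egg-diapausing grasshoppers, the day adults first appear in
a season is well predicted by when the season's cumulative thermal time —
growing degree-days (GDD) — crosses a species-specific requirement. That
makes a historical resurvey unusually interpretable: if a community's
first-adult dates have shifted over decades but the GDD totals at which
each species reaches adulthood have not, the phenological shift is
attributable to *when in the season* the required heat now arrives, rather
than to evolved changes in the species themselves.

`phenogdd` implements that whole chain of reasoning as testable code: a
single-sine degree-day engine, a data-driven calibration of the base
development threshold, the resurvey statistics (advancement, paired tests,
timing models, abundance correlations, elevation gradients), and a
synthetic weather/survey generator that lets every stage be validated
end-to-end without any station downloads.

## The single-sine degree-day model

A day's temperature course is approximated by one sine wave through the
daily minimum and maximum with a fixed 12-hour spacing. Daily degree-days
are the area between that curve and the base (development) threshold,
capped above at the upper threshold — the "horizontal cutoff", under which
time spent above the cutoff contributes at most `upper - base` per day.
With daily mean $m = (T_{\min}+T_{\max})/2$ and amplitude
$a = (T_{\max}-T_{\min})/2$, six analytic cases arise depending on where
the thresholds cut the curve; the intercepted cases use
$\theta = \arcsin((L - m)/a)$ terms in the closed-form integrals.

Defaults are a 12 °C base and a 38 °C cutoff. In montane grassland data
the cutoff essentially never binds (daily maxima stay below 38 °C), and
the engine preserves that property exactly: for any day with
$T_{\max} < 38$, results with and without the cutoff are identical.

Numerical choices:

* **Tie-breaking at exact threshold equality** (e.g. $T_{\max} = L$): the
  flatter branch is taken. The integrand is continuous there, so the choice
  cannot change the value; the test suite checks these boundaries against a
  quadrature oracle (trapezoidal integration of the clipped sine at 3-second
  resolution), which agrees with the analytic forms to better than
  $10^{-7}$ °C·day over randomized cases spanning all six branches.
* **Missing days** (absent rows, or a missing min or max) contribute 0 to
  accumulation and are counted; a year is dropped from baseline or decade
  statistics when any window month misses more than 3 days or the window
  misses more than 10 in total. Printed exclusion lists in historical
  studies rarely state their rule; this one is explicit and auditable via
  the per-year exclusion report.
* **Leap years**: day-of-year is taken from the real calendar (March 1 is
  day 60 or 61), and multi-year averaging aligns by calendar month-day, so
  February 29 can never enter a March–August window.

## Calibrating the base threshold

Grasshopper lower development thresholds plausibly lie between 10 and
17 °C. The calibration picks the candidate base that makes each species'
at-adulthood GDD most *consistent across survey years*: for each candidate,
compute every species' GDD at its first-adult day in each year, take the
per-species range across years, total the ranges over species (within each
site, summed across sites when pooling), and select the minimiser. Ties
resolve to the lower temperature (more conservative: more accumulation
days), with a warning; a single-year survey makes every spread zero and is
flagged degenerate. Species observed in one year only contribute zero
spread but remain in the report.

Two readings of "most similar across years" are possible — per site or
pooled across sites — so both are exposed; the default selects from the
pooled total, and the per-site minimisers are always reported.

The parameter-recovery experiment (`calibration_recovery()`) is worth
describing because the objective is not trivially well-behaved. The spread
total has an intrinsic drift toward high candidate bases: raising the base
compresses the GDD scale and leaves fewer accumulation days, so spreads
shrink for free. Recovering a known true base from synthetic events
therefore requires the data to carry real signal:

* the two survey years must actually differ climatologically — the default
  contrast is 3 °C in annual mean, comparable to the spread of seasonal
  means across observed years in this region; with near-identical years
  the objective is flat and no threshold is identifiable from it;
* the community must span the season. Early species (onsets where daily
  increments are small) discriminate between adjacent candidates, because
  their event-day GDD carries little day-discretization overshoot; late
  species (onsets in mid-to-late summer) are the only ones that penalise
  candidates far above the truth, whose sparse accumulation would otherwise
  mimic consistency.

The default experiment uses eleven species with requirements from 50 to
650 °C·day at a lower-montane site with 1 °C daily noise. Under those
conditions the modal selected base equals the generating base for every
truth in 10–17 (checked over disjoint seed ranges during design), with
per-seed recovery rates around 0.75–1.0 and misses landing on adjacent
1 °C candidates.

## Resurvey statistics

**First appearances and accidentals.** The first adult date of a species
in a year is accepted only if a late-instar juvenile (instar 4 or 5 by
default — "late instar" is not standardised, so the set is configurable)
was recorded at that site on or before that date; otherwise the next
qualifying adult date is used. This screens out adults blown in from lower
elevations, which would otherwise fake early emergence. Zero-count rows
mark visits and are never observations.

**Advancement and the sampling-window rule.** The baseline first-adult day
is the *earliest* day over the baseline years — a conservative choice, as a
resurvey date must beat the best historical date to register. Because the
baseline surveys were weekly, only shifts strictly exceeding 7 days count
as change; a 7-day shift is "no change". Deltas are resurvey minus
baseline, so advancement is negative.

**Tests.** The community-level test is a one-sample t on per-species
differences between the mean resurvey day and the baseline earliest day
(two-sided; zero-variance differences are flagged rather than forced).
The decade comparison is a pooled-variance two-sample t on yearly mean
seasonal temperatures (daily midpoints averaged over March–August), after
the completeness screen. The advancement-versus-timing model is
`delta ~ baseline_doy + year` with treatment-coded years and marginal
(type-II) F tests, so term order is irrelevant; no interaction is fitted by
default since none is expected to be reported, but a flag fits it.
Abundance changes use only each site's overlap window (the part of the
season sampled in both eras) and are compared by Spearman rank correlation
with average-rank ties — changes span orders of magnitude, so ranks are the
right scale. No multiplicity correction is applied anywhere, matching
standard practice in the source analyses.

**GDD regressions.** Past-versus-present at-adulthood GDDs are compared by
OLS with a t test of slope = 1 (conserved requirements); the community
mean requirement per site is regressed on elevation, reported signed and
as a magnitude. On the packaged resurvey tables this reproduces the
0.25 GDD-per-metre community decline (the computed $r^2$ is 0.96).

## The synthetic-data generator

`generate_weather()` builds daily series as: elevation-adjusted annual mean
(lapse 0.0065 °C/m from a 1752 m reference) + a seasonal sinusoid
(amplitude 12 °C, maximum near day 200, consistent with a Northern
Hemisphere March–August window) + a warming-scenario offset + Gaussian
day-to-day noise, with min/max at ±half the diurnal range (14 °C). These
defaults were chosen from regional climatology once, before any tuning
against tests; with them, season GDD totals at the four site elevations
come out near 1100 / 750 / 500 / 300 °C·day — the right magnitudes for
prairie through subalpine grasslands.

`warming_scenario()` adds a seasonal offset that is zero before an onset
day and ramps linearly to the full amount — the mechanism of interest is
the *timing*, not just the amount, of warming. `generate_survey()`
emulates weekly sweep-net visits: a species is recorded as a late instar
while its accumulated GDD sits between 60% and 100% of its requirement,
and as an adult from the crossing day on, with negative-binomial counts
(overdispersed, as field totals are) and per-visit detectability. Visit
grids share one day-of-year anchor across years so that timing changes in
the simulated resurvey are phenological, not artefacts of shifted
sampling.

What the generator deliberately does **not** emulate: autocorrelated
weather (each day's noise is independent), precipitation or snowmelt cues,
density dependence, demographic carry-over between years, and
mis-identification. Passing tests on this generator therefore demonstrate
that the pipeline's logic and statistics behave as designed under the GDD
developmental model — not that real communities obey that model; that is
the scientific claim of the resurvey literature itself.

**Warming-timing scenario.** `fig_warming_timing_scenario()` runs a
control year, an early-onset warming year and a late-onset warming year
for a 100-GDD and a 500-GDD species. Early-onset warming (default 3 °C
from day 60) advances both beyond the 7-day window; warming that begins
only at the early species' control emergence day advances the late species
alone. The community-scale version (`simulate_resurvey()` +
`advancement_timing_model()`) shows the same mechanism as a negative
advancement-versus-original-timing slope, and, with no warming, stays
entirely inside the sampling window (null fidelity).

## Problem sizes and reproducibility

All simulation experiments in the tests and the acceptance script use
modest sizes chosen for tight feedback loops: 10,000 randomized days for
the engine-versus-oracle check, 20 seeds per true base for calibration
recovery, and 20 seeds for each warming-timing experiment. Every stochastic
quantity is reproducible bitwise from its seed; scripts derive all
sub-seeds from one command-line seed.

## Known limitations

* The cross-year-spread calibration cannot identify a threshold from a
  single survey year or from years with near-identical weather, and its
  high-base drift means a sparse, early-season-only community can select a
  spuriously high base. The degenerate cases are flagged, not hidden.
* Divergence days depend on the chosen exceedance (5 °C·day) and
  persistence (7 days) parameters; published "began to differ" days come
  with no stated criterion, so ours is explicit and configurable rather
  than matched to any printed value.
* Statistics recomputed from printed, rounded advancement tables can
  differ from values computed on the underlying raw dates; where a printed
  statistic is not recoverable from its own printed table, the package
  reports what the table yields.
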