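---
title: "Thermal-time modelling and harvest forecasting with grapeheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time modelling and harvest forecasting with grapeheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapeheat)
```

## The model

Plant development between two phenological stages is modelled as the
accumulation of thermal time: an hour at temperature $T_h$ contributes

$$\mathrm{GDH}(T_h) =
  \begin{cases} 0 & T_h \le T_b\\
  T_h - T_b & T_b < T_h \le T_u\\
  T_u - T_b & T_h > T_u,\end{cases}$$

a day's growing degree days (GDD) are its 24 degree-hours divided by 24,
and a stage interval sums daily GDD. $T_b$ (base temperature) is the
temperature at and below which development is taken to stop; $T_u$ (upper
threshold) the temperature above which additional heat no longer
accelerates development. Both are statistical constructs fitted for a
genotype, not physiological switch points. The central assumptions are
the usual ones of linear thermal-time models: development rate is linear
in temperature between the cardinal points, the GDD requirement of a
genotype is constant across seasons and sites in the absence of stress,
and hourly air temperature is an adequate driver (no radiation, water or
management covariates).

Two conventions fix the arithmetic everywhere in the package:

* **Interval convention.** Accumulation between stages includes the start
  date's 24 hours and excludes the end date's, and `days` is the plain
  date difference. Stage intervals are then exactly additive (bud break
  to bloom plus bloom to harvest equals bud break to harvest), matching
  how stage-wise GDD and day totals sum in the reference tables. Whether
  the harvest day itself should contribute is genuinely ambiguous; the
  exclusive-end choice costs at most one day's GDD (about 15 GDD in
  mid-summer) and the forecaster uses the complementary inclusive rule,
  so generation and prediction invert each other exactly.
* **Rounding convention.** Printed day counts and accuracies are rounded
  half away from zero (so a mean absolute deviation of 13.5 days prints
  as 14, and 5.4 as 5). R's `round()` is half-to-even and would disagree
  on exactly these boundary cases.

## Estimating cardinal temperatures

Five classical criteria for $T_b$ are provided (`estimate_tb()`), all
computed from per-season summaries over the bud break → harvest interval:
least standard deviation of the per-season GDD totals, least SD in days
(the GDD spread divided by the grand mean of seasonal thermal excess
$\bar T_i - T_b$), least coefficient of variation of GDD, the root of the
least-squares slope of $\mathrm{GDD}_i$ on the seasonal mean temperature
$\bar T_i$ ("regression coefficient"), and the x-intercept of the
regression of development rate $1/d_i$ on $\bar T_i$. The cited
historical formulations express these criteria through the classical
shortcut $\mathrm{GDD}_i = d_i(\bar T_i - T_b)$; the exact closed forms
were not reprinted in the source tables we reproduce, so the package
evaluates each criterion on a fine temperature grid with GDD always
computed by the hourly engine. The shortcut is kept only as a
cross-check oracle (`gdd_mean_shortcut()`): on constant-temperature
fixtures the two must (and do) agree exactly. Sample SDs use the $n-1$
denominator throughout; this is what reproduces the published 5.52 % CV
from the open-field totals.

Numerical choices: the method grid spans $-5$ to $20$ °C at 0.01 °C
(two-decimal reporting precision); scan curves use 1 °C steps over
3–12 °C ($T_b$) and 25–45 °C ($T_u$), the ranges proposed for grapevine.
$T_b$ estimation runs **uncapped** and the $T_u$ scan then holds the
selected $T_b$ fixed, mirroring the sequential selection procedure; the
paired grid search (`paired_scan()`) explores both jointly and breaks CV
ties toward the smaller $T_b$, then the smaller $T_u$. The
regression-coefficient root is bracketed on the grid and refined
linearly; the x-intercept method needs no grid but requires a positive
rate-temperature slope.

### Identifiability

Two degeneracies matter in practice and are visible in the test suite.
First, when seasons differ little in mean temperature, the CV criterion's
minimum is dragged below the true base: lowering the trial $T_b$ inflates
all totals by a similar amount, which inflates the mean faster than the
SD. Realistic inter-annual variation (about 1 °C in seasonal level,
which the synthetic generator includes by default) restores a
well-localised minimum. Second, in a joint $(T_b, T_u)$ search, raising
the base and lowering the cap compensate almost exactly when seasons
differ only in level, leaving a flat CV ridge; the pair is identified
only when exposure to the cap varies across seasons independently of the
mean (in the validation fixtures, by crossing season mean with diurnal
amplitude). Season-subset instability of the five methods — the reason
the CV criterion is preferred in the literature — can be examined with
`subset_stability()`.

## Phenology and harvest calling

Stage dates are whole calendar days for BBCH 09 (bud break), 65 (full
bloom) and 89 (harvest), with ordering enforced. Harvest is called from
weekly berry samples as the date of the first sample whose maturation
index — total soluble solids (°Brix) over titratable acidity (g/L
tartaric acid) — exceeds 18. The sources describe the rule both as
"above 18" and as "reaching 18"; the package defaults to the strict
inequality and exposes `strict` as a flag. The crossing is attributed to
the sampling date itself, not interpolated between samples, since
harvest decisions are taken at sampling resolution.

## Forecasting

`predict_harvest_gdd()` accumulates daily GDD from the bud-break date
(inclusive) along observed weather or a reference year and returns the
first date reaching the requirement; `predict_harvest_calendar()` adds
the historical mean cycle length to the bud-break date. Deviations are
predicted minus observed (negative = predicted early), and accuracy is
the half-up-rounded mean absolute deviation per method. The default
requirement is the plain multi-season mean applied to every season — the
in-sample convention of the study being reproduced — with an honest
leave-one-out mode available
(`leave_current_out_requirement(..., exclude_target = TRUE)`).

Reference years (`build_average_year()`) are slot-wise means over
(month, day, hour) on a 365-day grid: Feb 29 is dropped when building
and, when a projection crosses a Feb 29, that day contributes zero GDD
(it holds no slot) while remaining a calendar day. Projections crossing
Dec 31 wrap into the same reference year's January, treating it as
cyclic. Construction of typical meteorological years is out of scope;
any provided reference year is consumed via the same CSV dialect.

Missing station hours are the package's own policy (the sources are
silent): gaps of at most `max_gap` hours (default 6) are linearly
interpolated and flagged, longer gaps refuse — degree-day totals across
an unobserved day would be silently wrong. Temperatures outside a
plausibility window (default $-30$ to $+60$ °C, configurable) are
rejected at read time; the window is wide enough for greenhouse extremes
while catching sensor glitches.

## The synthetic generator

`generate_weather()` emulates the El Ejido station climate:

| parameter | default | meaning |
|---|---|---|
| `annual_mean` | 18.5 °C | long-term mean (open field) |
| `annual_amplitude` | 7 °C | seasonal half-range; minimum mid-January |
| `diurnal_amplitude` | 10 °C (15 °C greenhouse) | daily range; minimum pre-dawn |
| `noise_sd` | 1.5 °C | marginal SD of hourly noise |
| `ar_coefficient` | 0.9 | AR(1) persistence of the noise |
| `interannual_sd` | 1 °C | SD of the per-year level shift |

AR(1) noise (rather than white) reflects the hour-to-hour persistence of
real air temperature; white noise would be unrealistically rough and
makes threshold recovery artificially easy. The inter-annual level shift
reproduces the fact that real seasons differ (the reference data span a
coolest and a warmest season 18 days apart in cycle length); it is also
what makes the estimation criteria identifiable, as discussed above.
Explicit `year_offsets` allow deterministic between-season contrast for
noiseless validation. Bud break is fixed by date (15 March open field,
20 January under plastic, where covering advances the cycle start).

`generate_phenology()` applies a virtual cultivar's exact thermal-time
rule (defaults: cardinal temperatures 5/30 °C, requirements 694 GDD to
bloom plus 939 GDD to harvest, i.e. the fitted open-field values), so
recovery tests have known truth, and `generate_maturation_series()`
builds weekly maturation samples whose index first exceeds 18 exactly on
the harvest date. What the generator does **not** emulate: radiation and
humidity, chilling accumulation and rest-breaking, within-season weather
regimes (heat waves, cold spells with persistent sign), management
effects, or biological noise in the requirement itself. Passing recovery
tests therefore show the estimators are correct and well-conditioned
under the stated climate structure — not that five real seasons suffice
to pin the cardinal temperatures of a real cultivar; the published
season-subset instability is a caution in exactly that direction.

## Validation set-up and known limitations

The test suite validates against an independent brute-force hour-loop
oracle (agreement to $10^{-9}$), checks monotonicity of GDD in both
cardinal temperatures, round-trip exactness of generation vs prediction,
and parameter recovery: all five $T_b$ estimators within 0.5 °C on
noiseless five-season sets (season means spread ±2 °C), within 1 °C on
average over 10 seeds at 1 °C noise, the upper-threshold scan minimum
within 2 °C of truth, the requirement within 2 %, and the paired scan
within 1 °C of a (7, 31) truth on nine crossed seasons. Simulation sizes
(five to nine seasons of one hourly year each; 10–20 seeds per property)
were chosen so each estimate rests on the same data volume as the field
study it mirrors while keeping the whole suite quick to run.

Limitations worth keeping in mind: the linear model is an approximation
to a sigmoid response, and requirement estimates transfer poorly between
environments (the greenhouse requirement is about 6 % lower than the
open-field one — the package reproduces that recalibration rather than
explains it); accuracy degrades in seasons that deviate strongly from
the reference year; and all per-season reference GDD values are consumed
as published inputs, since the underlying hourly station records were
never deposited — table-level arithmetic is reproducible, the raw
accumulation behind those specific numbers is not.
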