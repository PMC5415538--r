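---
title: "Analysing five decades of shorebird morphometrics with wingtrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing five decades of shorebird morphometrics with wingtrends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingtrends)
```

## The problem

Shorebird banding programmes accumulate wing- and bill-length measurements
over decades, but the series are awkward to analyse directly: sample sizes
per site and year range from a handful of nest-trapped breeders to several
thousand migrants, measurement techniques differ between programmes
(flattened versus natural wing chord; exposed-culmen versus narina bill
measurements), museum specimens shrink after preparation, and the sexes —
which differ in size, with females larger — cannot be reliably separated in
the field. wingtrends packages a consistent workflow for this situation,
built around five-decade records of semipalmated sandpipers
(*Calidris pusilla*) at five Arctic breeding sites and three southbound
stopover sites, plus 139 earlier museum specimens.

The central scientific quantities are: the annual rate of change of mean
wing length (mm/yr) within and across breeding regions; the historical
baseline against which the earliest live samples are compared; standardized
evolutionary rates (darwins, haldanes) that make the change comparable
across studies; and the bill-on-wing allometric slope, whose own time trend
distinguishes a change in overall size from a change in shape.

## Unit of analysis and trend models

All trend fitting uses the **annual mean per site or region** as the unit of
analysis, with unweighted ordinary least squares. With raw records, a single
year with several thousand captures would dominate every fit and p value;
the annual-mean convention equalizes power across sites with very different
effort. We verified that the packaged data reproduce the published slope
table only under unweighted fits, which settles the convention.

Three models are provided:

* `fit_linear()` — `mean ~ year`, requiring at least four annual means
  (`min_years = 4`, overridable) because shorter series carry almost no
  trend information.
* `fit_quadratic()` — `mean ~ year + year^2`. Raw calendar years make the
  quadratic design matrix nearly singular (condition numbers around
  `1e13`), so fitting is done on years centered at their mean and the
  coefficients are converted back to the uncentered calendar-year
  convention for reporting, with standard errors propagated through the
  linear transformation. A test guards the equivalence of the two
  parameterizations to below `1e-6` mm in fitted values. `peak_year()`
  reports the vertex `-b/(2c)`, labelled a maximum only when the quadratic
  coefficient is negative, and refuses vertices when `|c|` is below
  tolerance (default `1e-10`).
* `ancova_trend()` — `mean ~ region + year` versus
  `mean ~ region * year`. The interaction F tests whether regions share a
  common rate; the reduced model provides the common slope (with
  region-specific intercepts absorbing the well-known east–west size
  cline). Regions contributing a single year are dropped with a warning.

On the packaged data the computed vertex of the early stopover quadratic is
1978.9; we report the computed value rather than the rounder narrative year
sometimes quoted for this series.

Method contamination is treated as an error, not a warning: any fit or
pooling operation that mixes flattened-chord, natural-chord or
unknown-technique wing series stops, because the 2–4 mm method offset
exceeds the 35-year trend signal itself. Exclusions (limited-effort years,
technique changes, one duplicated site record) are encoded as
`trend_eligible`/`exclusion_reason` data flags in the table, never as
hard-coded site lists, so alternative inclusion analyses are a data edit.
Two inclusion decisions were genuinely open and are resolved as follows:
the record from the Rasmussen site duplicates the Mackenzie Delta 1994 row
verbatim and is flagged ineligible, which is also the only reading
consistent with the published ANCOVA degrees of freedom (32 means); and the
eastern series includes the 2015 Coats Island mean (13 points) for the same
df-arithmetic reason, although the published year label for that row reads
1980–2014. Similarly, the stopover culmen quadratic is fitted on 18 means
with the 1984 limited-effort year excluded — the published residual df
(`F[1,15]`) is consistent only with 18 points, although the text describes
the 1984/2006 exclusions as applying to wings alone.

## Pooling and period contrasts

`pool_weighted()` combines annual summaries into one pooled mean, SD and
SE. Raw records are unavailable for most series, so each year's
individual-level variance is reconstructed from its standard error
(`sd^2 = n * se^2`) and combined with the between-year component as a
grouped-data variance. This is exact when the summaries came from
`summarize_annual()` (a property test asserts bit-level agreement with
summarizing the concatenated records) and is a documented approximation
otherwise: on the packaged stopover contrast it reproduces the published
2.16 mm difference as 2.15 mm, and published raw-data t statistics can
differ a few percent from the reconstructed ones. `period_contrast()` runs
a pooled-variance two-sample t on the reconstructed groups.

## Historical baselines and resampled comparisons

Museum specimens are sexed; live field samples are not, but nest-trapping
of this biparental species yields sex-balanced samples. The comparable
baseline is therefore built by `simulate_baseline()`: draw 1,000 males and
1,000 females from per-sex normal distributions and pool them. The per-sex
museum statistics behind the published pooled values are not reprinted in
the compilation, so the packaged workflow inverts the mixture moments with
`calibrate_sex_stats()` — sexes at `pooled_mean ± offset/2` with common
within-sex SD `sqrt(pooled_sd^2 - offset^2/4)` — which reproduces the
printed pooled mean and SD by construction. Dimorphism as a pure location
shift with common SD is the simplest model consistent with female-biased
dimorphism, and is deliberately replaceable.

Because only a few dozen museum specimens stand behind each baseline, a
single test of the full 2,000-value pool against a large live sample would
overstate power. `resampled_comparison()` instead draws, per replicate, a
with-replacement sample from the realized pool with `n` equal to the
original museum specimen count, t-tests it against the live sample, and
averages t and p over 30 replicates (raw averaging of p values; whether to
average on the t scale instead is unspecified in the source and makes no
qualitative difference). Sampling from the realized pool rather than
re-drawing from the parametric normal mirrors the published procedure; the
mean difference is computed from full means and is therefore independent of
the resampling seed. When only live summary statistics exist, a Gaussian
live sample of size `n` and SD `se*sqrt(n)` is reconstituted — the source
of small discrepancies (on the order of 0.2 mm) against published
differences computed from raw data. Every stochastic operation takes and
records a seed; identical seeds give bit-identical results. The Student
pooled-variance t is the default (the Welch variant is a switch), and the
degenerate zero-variance cases are defined explicitly rather than left to
produce NaN.

## Evolutionary rates

`haldanes()` is `(delta / pooled_sd) / (span / generation_time)`: with the
packaged defaults (pooled wing SD 2.916 mm across breeding populations and
years; generation time 4.67 years from demographic data) a 3.85 mm decline
over 35 years is 0.176 haldanes. `darwins()` offers both the log-ratio form
`|ln(x1) - ln(x2)| / t_Myr` and the proportional form
`(|delta|/start) / t_Myr`; they agree to first order (a test bounds the
disagreement at 1% for relative changes under 1%), but only the
proportional form with a reference length near 100.2 mm reproduces the
published 1,098 darwins for these data (the log-ratio form gives ≈1,120
from any plausible start/delta pair), so proportional is the default.
Both the pooled SD and the generation time are arguments, not constants.
Both rates are invariant under common rescaling of the length inputs, and
that invariance is tested.

## Allometry

`cov_slope()` computes the sample covariance (n−1 denominator) of paired
wing/culmen measurements and the OLS slope of culmen on wing; the
`slope = cov/var(wing)` and `slope = r * sd(culmen)/sd(wing)` identities
are asserted on every test input. `mean_slope()` is the unweighted mean of
per-sample slopes (0.223 on the packaged table). `slope_trend()` regresses
the slopes on their period midpoints, weighted by the raw number of pairs
("weighted by sample size" read literally, not as `sqrt(n)`). Period
midpoints are the arithmetic mean of the calendar years listed for the
period (`"1991-1992, 1994"` → 1992.33); the published regression is
insensitive to midpoint rounding at its printed precision, and the packaged
reproduction lands within 2% of the published −0.0056/yr. Because the
published covariance table prints slopes without SEs, `slope_trend()`
accepts precomputed summary tables so that analysis is reproducible without
individual records.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` fixes the study conditions; `generate_individuals()`
and `generate_annual_table()` realize them. Defaults:

| Parameter | Default | Basis |
|---|---|---|
| regional pooled wing mean ± SD | west 96.66 ± 2.48, central 97.40 ± 3.03, east 99.34 ± 2.92 mm | packaged historical rows |
| regional pooled culmen mean ± SD | 18.27 ± 1.02, 18.86 ± 1.18, 20.65 ± 1.25 mm | packaged historical rows |
| dimorphism (F − M) | wing 2.5 mm, culmen 1.2 mm | consistent with the ~2 mm shift seen when sex ratios change seasonally; bill dimorphism is proportionally larger in this species |
| wing trend | +0.05 mm/yr to a 1980 breakpoint, −0.11 mm/yr after | ≈1.5 mm pre-1980 rise over three decades; published common decline |
| culmen trend | flat | no consistent published change |
| natural-chord offset | −2.5 mm (constant) | midpoint of the stated 2–4 mm; a proportional option exists |
| allometric slope | 0.223 at 1995, −0.0056/yr | published mean slope and its time trend |
| sex ratio | 0.5, optional logistic date bias (females earlier) | females depart breeding grounds first |
| birds per site-year | 100 | typical breeding-study effort |

Culmen values are coupled to each bird's wing deviation through the
allometric slope, with the residual SD chosen so the configured pooled
culmen SD is preserved. Tests use the generator as ground truth: a
programmed −0.11 mm/yr decline is recovered within 2 SE, a programmed
rise-then-fall puts the fitted quadratic vertex within a few years of the
breakpoint, and the 95% CI of the fitted slope covers the programmed slope
at the nominal rate over 1,000 simulated 30-year series.

The generator is deliberately simpler than reality in ways that bound what
passing tests show: annual means are exchangeable draws (no autocorrelated
environmental noise, so the nominal CI coverage seen in tests is optimistic
for real series); observers are a fixed per-site offset rather than a
turnover process; stopover composition is a static mixture with no
mass- or morphology-dependent habitat shifts; and wing wear, age structure
and within-season growth are absent. Conclusions about the real series rest
on the packaged published summaries, not on the generator.

## Numerical and reporting conventions

Internal precision is full floating point throughout; rounding to printed
precision (2 decimals for means, 3 for slopes, p values floored at
`"<.001"`) happens only in the reporting layer (`trend_table()`,
`comparison_table()`, `covariance_table()`, `format_p()`). No
multiple-testing correction is applied across the many regressions,
matching the source analyses; all p values are two-sided. Report writers
emit files atomically and pair them with a `run_manifest()` recording
command, configuration hash, input checksums, seeds and package version.

Test problem sizes were chosen to keep the full suite under a few minutes
on one CPU: mixture-moment and round-trip checks use `1e5` draws,
null-uniformity of the resampled p values uses 1,000 replicates, and the
coverage study uses 1,000 simulated series of 30 years.

## Known limitations

* The per-sex museum statistics are calibrated from pooled values, not
  transcribed from the original specimen source, so resampled t and p
  values match the published comparison table only approximately; the mean
  differences, which do not depend on that calibration, reproduce well.
* One published stopover culmen quadratic coefficient (|linear| 8.49)
  could not be reproduced from the printed annual means under any
  single-year exclusion we examined (the recomputation on the 18 eligible
  means gives 8.26, with the published equation internally inconsistent at
  its printed precision); the package reports the recomputed value.
* Capture-date-adjusted annual means (an alternative to excluding
  limited-effort years) are out of scope; the source reports that both
  approaches give similar results.
* No mixed-effects or autocorrelation-aware time-series models: the
  published analyses use plain OLS, and the package follows them.
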