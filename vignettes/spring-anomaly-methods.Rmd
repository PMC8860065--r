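---
title: "Methods: the Annual Anomaly of spring migration and its climate attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Annual Anomaly of spring migration and its climate attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springAnomaly)
```

## The problem

Long-distance passerine migrants such as the Willow Warbler pass
coastal ringing stations in a stream that mixes populations from
different wintering regions. Daily capture totals over a fixed spring
window are the raw record of that passage. Two questions drive the
analysis this package implements: *has the timing of passage shifted
across decades*, and *which climate conditions — at the wintering
grounds, at stopovers, locally — explain the year-to-year variation,
and in which part of the season does each operate?*

Point summaries (first arrival, median date) discard most of the
information in a passage curve and are sensitive to effort and sample
size. The Annual Anomaly instead compares whole cumulative curves, and
its decomposition localises timing signals within the season.

## The model and its assumptions

### Counts to curves

For each spring, captures are deduplicated to the first capture of
each individual in the season, tallied per calendar day of the fixed
window (1 April–15 May, 45 days), converted to percentages of the
season total, and cumulated. Using percentages gives each year equal
weight in the multiyear baseline regardless of how many birds were
caught; the baseline is the unweighted elementwise mean of the year
curves. Seasons with fewer than 30 birds are excluded entirely —
from the anomaly series *and* from the baseline — because a
percentage curve built from a handful of captures is mostly noise.
The threshold is inclusive (`total >= 30` is kept): with the
deposited study data this excludes exactly the two documented
low-effort springs.

### The anomaly

For year *y* and day range *D*,

$$AA_y(D) = \sum_{d \in D} \frac{\bar C(d) - C_y(d)}{100}.$$

Each summand is a dimensionless proportion shortfall accumulated over
one day, so the sum is in days. The sign convention is **positive =
later than baseline**: if the year's curve runs below the baseline the
year's passage is lagging. We chose this orientation because it makes
two companion results internally consistent — negative regression
coefficients then mean "higher climate index, earlier passage", and
positive juvenile-regression slopes mean "later passage after
productive autumns". The source literature contains one sentence
implying the opposite orientation; since the two conventions differ
only by sign, `run_config(sign_flip = TRUE)` flips every anomaly
rather than guessing intent.

The anomaly is a plain daily sum, not a trapezoid integral: cumulative
curves are step functions on calendar days and the decomposition logic
needs exact additivity over day ranges.

### Percentile periods

Dates are bound to percentiles of the *baseline* curve by the
first-crossing rule `min{d : C̄(d) ≥ q}`. Three design points matter:

* **Integer bounds as printed.** The conventional thirds are 0–33,
  34–66, 67–100 percent and the sub-period grid is 0–20, 11–30, 21–40,
  …, 81–100 — integer percentile bounds, not 33.33/66.67, and the
  11/21/31-style lower bounds of the overlapping grid are taken as
  printed rather than the rounder 10/20/30 phrasing sometimes used to
  describe it.
* **Contiguity for main periods.** MP2 starts one day after MP1's
  upper date (and so on), so MP1–MP3 partition the window exactly and
  their anomalies sum to the overall AA to floating tolerance. The
  overlapping sub-periods instead use each range's own lower-percentile
  crossing.
* **The 100% bound owns the tail.** A baseline can flatten at 100
  before the window's last day (every included year finished). The
  closing period still extends to the window end; otherwise tail days
  with activity in a *new* year would belong to no period and
  additivity would fail.

### Regression machinery

Response and covariates are standardised to mean 0, SD 1 over exactly
the years entering a given model (not over all available years; with
listwise-dropped years the two differ, and per-model standardisation
keeps every fitted model internally z-scaled). All-subsets OLS is
ranked by AICc with parameter count `k = p + 2` (slopes + intercept +
residual variance), matching the convention of the common R
model-selection tooling so rankings are comparable. Ties within 1e-9
prefer the smaller model, then predictor names; subset enumeration is
binary counting in roster order, so logs are reproducible. A subset
whose AICc correction would divide by zero (`n − k − 1 < 1`) is
skipped with a warning rather than reported on a different scale.
An essentially exact fit (RSS below 1e-12 of the response's sum of
squares) is given infinite likelihood so perfect submodels rank ahead
of their supersets deterministically instead of by machine noise.

Partial correlations are computed definitionally — the correlation of
the two residual vectors after regressing response and focal predictor
on the remaining predictors — and the identity `pR = t/√(t² + df)` is
used as an independent cross-check in the test suite, never as the
implementation. "Contribution" of a variable to a top-model set
(ΔAICc < 2, strict) is its presence frequency by default; an
Akaike-weight-sum variant is provided because the phrase is ambiguous
in the literature, and presence frequency was chosen as the default
because stated percentages like "contributed at least 60%" read most
naturally as model counts.

Collinear covariate pairs (|r| ≥ 0.7 by default; the threshold is a
config knob because "highly correlated" is conventionally left
undefined) are screened greedily: the member with the lower top-model
contribution is dropped, ties keep the variable listed earlier in the
roster.

The nine-sub-period profile refits the **full** selected-variable
model for every sub-period and stores sign-inverted partial
correlations (−pR), so the plotted quantity is positive when a higher
index means earlier passage. The full-model reading (rather than
per-sub-period best subsets) keeps the nine columns comparable — the
profile is a moving-window *display*, not nine independent inferences;
the windows overlap by construction.

Year trends use per-period OLS on calendar year with Benjamini–
Hochberg correction across the family of tests reported together (the
four period series by default). The total shift over the study is
`|slope| × (last − first)` years — 35 for a 36-season study; phrases
like "over the 36 years" are ambiguous by one slope-unit, which the
reporting tolerance absorbs.

### Juvenile index and recoveries

Autumn productivity is proxied by juveniles caught per 50 nets
(season juvenile total / nets × 50); the square-root transform is
applied to this *normalised* index, not the raw count, because the
effort correction must precede the variance-stabilising transform.
The documented outlier autumn is excluded by an explicit
configuration list — the exclusion is a judgment call, and automating
it would hide that. Direct-recovery speed is the mean of per-pair
distance/elapsed-days; coordinates are resolved on a spherical earth
(haversine, R = 6371 km) and sub-day elapsed times round up to one
day.

## The synthetic world

`gen_study()` emulates the data-generating structure the analysis
assumes: spring passage is a weighted mixture of sequential cohorts
(early/mid/late, mirroring populations from different wintering
regions), each cohort's mean transit day responding linearly — in days
per standard deviation — to named seasonal climate covariates, plus
1 day of year-to-year jitter. Daily counts are a multinomial draw of a
negative-binomial season total from the day-discretised, truncated and
renormalised Gaussian mixture. Defaults mirror the study scale: 36
years from 1982, 45-day window, ~30–600 birds per spring, nine
covariates with negative effects (higher index, earlier passage), mild
upward trends on the Sahel autumn indices and local spring temperature,
two springs forced below the 30-bird filter, 15% within-season
recaptures, an autumn juvenile series over 38–76 nets with one
five-fold outlier autumn, and ~25 direct recoveries at 66 ± 8 km/day.

Monthly climate values are drawn so the *seasonal mean* recovered
through the package's own windowing is exactly the drawn yearly value
(monthly texture is centred within the window); variables are mutually
independent unless configured otherwise. A single root seed fans out
into named substreams per (component, year), so adding a year never
perturbs earlier years' draws and equal configs produce byte-identical
files.

What the generator does *not* emulate — and therefore what a green
test does not establish: weather-dependent daily catchability, within-
spring effort variation, spatial structure, correlated climate
indices, non-Gaussian cohort shapes, and overdispersion beyond the
multinomial. A pipeline validated here is validated for its
*arithmetic and inference machinery*, not for robustness to those
field realities.

## Numerical choices and degenerate inputs

* Percentile crossings use a 1e-9 tolerance so a curve ending at
  100 within floating error still crosses `q = 100`.
* Zero-total seasons are a domain error at curve construction; the
  pipeline filters them before that point.
* Zero-variance standardisation, degenerate partial-correlation
  residuals, rank-deficient designs (reported with the aliased column
  names) and empty day spans (reported with the period label) all stop
  with explicit messages rather than propagating NaN.
* A perfectly flat anomaly series has slope 0 and p = 1 by definition
  rather than a machine-noise t-ratio.
* Truncation of a cohort's Gaussian beyond the window is renormalised;
  when more than 25% of a cohort's mass falls outside, the generator
  warns (truncation distorts the injected effect near the window
  edges).

## Costs

The full 16-candidate enumeration (65,536 fits at n ≈ 34) takes
~25–30 s per response on one CPU; the test suite restricts candidate
sets so the whole suite runs in under 10 s. The two-cohort recovery
scenario (40 years × 2,000 birds) runs in well under a minute
end-to-end.

## Known limitations

* The anomaly is bounded by its period length, so extreme years
  saturate; the statistic is a timing summary, not a likelihood.
* Overlapping sub-period fits reuse the same years nine times;
  their pR values are a display and carry no joint error control.
* The collinearity screen is greedy, not optimal; with more than a
  few tightly-correlated variables an exhaustive screen could retain
  a different (larger) admissible set.
* Reproduction of the published summary numbers requires the deposited
  ringing dataset, which cannot be shipped with the package; the
  acceptance tests that need it fail with an explanatory message
  rather than silently skipping.
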