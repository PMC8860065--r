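# springAnomaly

Quantify the timing of bird spring migration from daily ringing-station
capture counts, and attribute year-to-year timing shifts to large-scale
climate indices.

The package is written for migration ecologists working with
capture–mark (mistnetting) data: daily totals of a species over a fixed
spring window (1 April–15 May by default), collected across decades.
Such series are too noisy on any single day to date "arrival", so the
package works with whole seasonal passage curves instead.

## The statistic

Daily counts for each spring are converted to percentages of that
season's total and cumulated into an arrival curve `C_y(d)` ending at
100%. Averaging the curves over years with equal weight gives the
multiyear baseline `C̄(d)`. The **Annual Anomaly** (in days) of year `y`
over a day range is

    AA_y = Σ_d ( C̄(d) − C_y(d) ) / 100

Positive values mean passage ran later than the multiyear average. The
baseline's percentile crossings define date ranges that decompose the
anomaly: three non-overlapping *main periods* (0–33, 34–66, 67–100% of
passage; they partition the window, so their anomalies sum exactly to
the overall AA) and nine overlapping 20-percentile *sub-periods* used
for moving-window attribution.

On top of that sit the attribution tools: all-subsets OLS ranked by
small-sample AICc, top-model sets (ΔAICc < 2) and per-variable
contributions, partial correlations `pR` and variance inflation
factors, year-trend tests with Benjamini–Hochberg correction, and the
nine-sub-period partial-correlation profile that shows each climate
index waxing or waning through spring.

A seeded synthetic-data generator (`gen_study()`) emulates the whole
stated world — sequential migratory cohorts whose mean transit dates
respond to known climate forcing, variable season totals, recaptures,
autumn juvenile counts with net-effort variation — so every stage of
the pipeline is testable with recoverable truth and no external data.

## Worked example

```r
library(springAnomaly)

cfg <- scenario_config(seed = 1)           # 36 synthetic springs, 1982-2017
dir <- tempfile("study-")
gen_study(cfg, dir = dir)

rc <- run_config(captures = file.path(dir, "captures.csv"),
                 effort   = file.path(dir, "effort.csv"),
                 climate  = file.path(dir, "climate.csv"),
                 roster   = file.path(dir, "roster.csv"),
                 out_dir  = tempfile("out-"),
                 exclude_autumn_years = 1982, seed = 1)
an <- run_anomaly(rc)
#> anomaly stage: 34 seasons included, 2 excluded (1993, 2011)
subset(an$periods, label %in% c("MP1", "MP2", "MP3"))
#>   label pct_lo pct_hi day_lo day_hi
#> 2   MP1      0     33      1     19
#> 3   MP2     34     66     20     31
#> 4   MP3     67    100     32     45
```

Two of the 36 simulated springs fall below the 30-bird threshold and
are excluded; the remaining 34 build the baseline. The main periods
partition the 45-day window at the baseline's 33rd and 66th percentile
dates (here 19 April and 1 May).

```r
m <- run_models(rc, an)
m$best$MP1
#> <regression_fit> MP1 ~ NAO APR-MAY + NAO NOV-MAR + PSAH AUG-OCT_1y +
#>                        TSAH AUG-OCT_1y + IOD AUG-OCT_1y + SOI AUG-OCT_1y + Year
#>   n = 34, AdjR2 = 0.849, AICc = 48.67
#>         predictor Estimate     SE     t        p  VIF    R2     pR
#> 1     NAO APR-MAY   -0.276 0.0810 -3.41 2.15e-03 1.43 0.309 -0.556
#> ...
#> 6  SOI AUG-OCT_1y   -0.767 0.0800 -9.60 4.96e-10 1.39 0.780 -0.883

round(m$profile$matrix[, c("SOI AUG-OCT_1y", "TLEB APR-MAY")], 2)
#>     SOI AUG-OCT_1y TLEB APR-MAY
#> SP1           0.87         0.05
#> SP2           0.83         0.56
#> SP3           0.66         0.75
#> SP4           0.26         0.83
#> SP5           0.00         0.85
#> ...
#> SP9          -0.27         0.76
```

The profile stores sign-inverted partial correlations (−pR), so
positive values mean "higher index, earlier passage". In the default
scenario the early cohort is timed by the previous autumn's Southern
Oscillation Index and the mid/late cohorts by local spring
temperature — and that is exactly the pattern the profile recovers:
the SOI column fades after early spring while the temperature column
rises and stays.

Negative coefficients throughout the best-model table mean earlier
passage with a higher climate index; the generator injected them that
way, mirroring the convention of the field. `m$trends` holds the
year-trend tests with BH-adjusted p-values, and `m$juvenile` the
regressions of each period's anomaly on the square root of the
previous autumn's juveniles-per-50-nets index.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/springAnomaly.R", package="springAnomaly"))') \
    simulate --out=study --seed=1
# then: anomaly / models / recover with the same --out
```

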