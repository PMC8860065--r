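Package: springAnomaly
Title: Annual-Anomaly Decomposition of Bird Spring-Migration Timing from
    Daily Capture Counts
Version: 0.1.0
Authors@R:
    person("Bird Migration", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the timing of bird spring migration from daily
    ringing-station capture counts via an Annual Anomaly statistic (in
    days) computed against a multiyear average cumulative arrival curve,
    decomposes the anomaly into percentile-defined main periods and
    overlapping sub-periods, and attributes year-to-year timing variation
    to large-scale climate indices through all-subsets AICc model
    selection, partial correlations, variance inflation diagnostics, and
    moving-window partial-correlation profiles.  Includes a seeded
    synthetic-data generator that emulates multi-cohort passage under
    known climate forcing so the full pipeline can be verified without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
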