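test_that("cumulative_percent turns counts into a percentage curve", {
  expect_equal(as.numeric(cumulative_percent(c(2, 3, 5))), c(20, 50, 100))
  expect_equal(as.numeric(cumulative_percent(c(1, 1, 1, 1))),
               c(25, 50, 75, 100))
  pm <- cumulative_percent(c(5, rep(0, 44)))
  expect_equal(as.numeric(pm), rep(100, 45))
  expect_error(cumulative_percent(rep(0, 45)), "positive")
  expect_error(cumulative_percent(c(-1, 2)), "non-negative")
})

test_that("multiyear_baseline is the equal-weight elementwise mean", {
  b <- multiyear_baseline(list(c(20, 50, 100), c(40, 70, 100)))
  expect_equal(as.numeric(b), c(30, 60, 100))
  same <- multiyear_baseline(list(c(25, 50, 100), c(25, 50, 100)))
  expect_equal(as.numeric(same), c(25, 50, 100))
  expect_error(multiyear_baseline(list(c(20, 100))), "at least 2")
  expect_error(multiyear_baseline(list(c(20, 100), c(10, 50, 100))),
               "mismatched")
})

test_that("annual_anomaly sums baseline-minus-curve over the day range", {
  base <- c(50, 80, 100); curve <- c(20, 60, 100)
  expect_equal(annual_anomaly(curve, base), 0.5)       # (30+20+0)/100
  expect_equal(annual_anomaly(curve, base, 1, 1), 0.3)
  expect_equal(annual_anomaly(base, base), 0)
  expect_error(annual_anomaly(curve, base, 2, 1), "invalid day range")
  expect_error(annual_anomaly(curve, base, 0, 3), "invalid day range")
})

test_that("anomaly is antisymmetric in curve and baseline", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_curve(); b <- random_curve()
    expect_equal(annual_anomaly(a, b), -annual_anomaly(b, a), tolerance = 1e-12)
  }
})

test_that("percentile_date applies the first-crossing rule", {
  base <- c(50, 80, 100)
  expect_equal(percentile_date(base, 33), 1L)
  expect_equal(percentile_date(base, 80), 2L)
  expect_equal(percentile_date(base, 100), 3L)
  expect_error(percentile_date(base, 0), "percentile")
  expect_error(percentile_date(base, 101), "percentile")
})

test_that("build_periods binds percentiles to day ranges", {
  base <- c(50, 80, 100)
  mp <- build_periods(base, main_period_ranges(), contiguous = TRUE)
  expect_equal(mp$day_lo, c(1L, 2L, 3L))
  expect_equal(mp$day_hi, c(1L, 2L, 3L))

  # overlapping sub-period rule uses pct_lo's own crossing
  sp <- build_periods(base, data.frame(label = "S", pct_lo = 51L,
                                       pct_hi = 90L))
  expect_equal(sp$day_lo, 2L)
  expect_equal(sp$day_hi, 3L)

  # a degenerate range errors with its label
  degenerate <- c(100, 100, 100)
  expect_error(build_periods(degenerate, main_period_ranges(),
                             contiguous = TRUE), "MP2")
})

test_that("main periods partition the window for random baselines", {
  set.seed(41)
  for (i in 1:20) {
    base <- multiyear_baseline(replicate(8, random_curve(), simplify = FALSE))
    mp <- build_periods(base, main_period_ranges(), contiguous = TRUE)
    expect_equal(mp$day_lo[1], 1L)
    expect_equal(mp$day_hi[3], length(base))
    expect_equal(mp$day_lo[2:3], mp$day_hi[1:2] + 1L)
  }
})

test_that("decompose_anomaly splits the toy anomaly as stated", {
  base <- c(50, 80, 100); curve <- c(20, 60, 100)
  periods <- data.frame(label = c("P1", "P2"), pct_lo = c(0L, 34L),
                        pct_hi = c(33L, 100L), day_lo = c(1L, 2L),
                        day_hi = c(1L, 3L))
  dec <- decompose_anomaly(curve, base, periods)
  expect_equal(dec$aa_days, c(0.3, 0.2))
  expect_equal(sum(dec$aa_days), annual_anomaly(curve, base))

  zero <- decompose_anomaly(base, base, periods)
  expect_true(all(zero$aa_days == 0))
})

test_that("main-period anomalies conserve the full-window anomaly", {
  set.seed(51)
  for (i in 1:50) {
    curves <- replicate(6, random_curve(), simplify = FALSE)
    base <- multiyear_baseline(curves)
    mp <- build_periods(base, main_period_ranges(), contiguous = TRUE)
    for (cv in curves) {
      dec <- decompose_anomaly(cv, base, mp)
      expect_equal(sum(dec$aa_days), annual_anomaly(cv, base),
                   tolerance = 1e-9)
    }
  }
})

test_that("translating counts k days later shifts AA by exactly k", {
  set.seed(61)
  counts <- integer(45)
  counts[5:20] <- rpois(16, 8) + 1
  base <- multiyear_baseline(replicate(5, random_curve(), simplify = FALSE))
  aa0 <- annual_anomaly(cumulative_percent(counts), base)
  for (k in c(1L, 3L, 10L, 25L)) {
    shifted <- c(integer(k), counts)[1:45]
    aak <- annual_anomaly(cumulative_percent(shifted), base)
    expect_equal(aak - aa0, k, tolerance = 1e-9)
  }
})

test_that("anomaly_table covers all years and honours the sign flag", {
  set.seed(71)
  curves <- replicate(4, random_curve(), simplify = FALSE)
  names(curves) <- 2001:2004
  base <- multiyear_baseline(curves)
  mp <- build_periods(base, main_period_ranges(), contiguous = TRUE)
  tab <- anomaly_table(curves, base, mp)
  expect_equal(nrow(tab), 12)
  flipped <- anomaly_table(curves, base, mp, sign_flip = TRUE)
  expect_equal(flipped$aa_days, -tab$aa_days)
})
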