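small_cfg <- function(...) {
  scenario_config(n_years = 8, start_year = 2000,
                  sub_threshold_years = 2003L,
                  season_total = list(mu = 120, size = 10), seed = 5, ...)
}

test_that("scenario_config validates its invariants", {
  expect_s3_class(small_cfg(), "scenario_config")
  expect_error(scenario_config(n_years = 3), "n_years")
  co <- springAnomaly:::.default_cohorts()
  co$early$weight <- 0.9
  expect_error(scenario_config(cohorts = co), "sum to 1")
})

test_that("gen_climate seasonal means are exactly recoverable from the CSV", {
  cfg <- small_cfg()
  clim <- gen_climate(cfg)
  X <- build_covariates(clim$monthly, clim$roster,
                        rownames(clim$seasonal))
  expect_equal(unname(X), unname(clim$seasonal), tolerance = 1e-9)
  # determinism
  clim2 <- gen_climate(cfg)
  expect_identical(clim$monthly, clim2$monthly)
})

test_that("a configured climate trend is recovered by OLS at large n", {
  cfg <- scenario_config(
    n_years = 200, start_year = 1801,
    climate = list(list(name = "TR APR-MAY", months = c(4, 5), lag_years = 0,
                        mean = 0, sd = 1, trend = 0.05, month_sd = 0.3)),
    cohorts = list(solo = list(weight = 1, base_mean_day = 23, sd_days = 5,
                               effects = c("TR APR-MAY" = 0))),
    seed = 12)
  clim <- gen_climate(cfg)
  yr <- as.numeric(rownames(clim$seasonal))
  slope <- coef(lm(clim$seasonal[, 1] ~ yr))[2]
  expect_equal(unname(slope), 0.05, tolerance = 0.01)

  # zero-sd, zero-noise spec gives a constant series
  cfg0 <- scenario_config(
    n_years = 6, climate = list(list(name = "C APR-MAY", months = c(4, 5),
                                     lag_years = 0, mean = 2, sd = 0,
                                     trend = 0, month_sd = 0)),
    cohorts = list(solo = list(weight = 1, base_mean_day = 23, sd_days = 5,
                               effects = c("C APR-MAY" = 0))),
    seed = 3)
  expect_equal(unname(gen_climate(cfg0)$seasonal[, 1]), rep(2, 6))
})

test_that("gen_passage conserves the multinomial total and centres correctly", {
  # symmetric single cohort at the window midpoint, no effects
  cfg <- scenario_config(
    n_years = 5,
    cohorts = list(solo = list(weight = 1, base_mean_day = 22.5, sd_days = 5,
                               effects = c("C APR-MAY" = 0))),
    climate = list(list(name = "C APR-MAY", months = c(4, 5), lag_years = 0,
                        mean = 0, sd = 1, trend = 0, month_sd = 0.3)),
    mean_noise_sd = 0, seed = 9)
  z <- c("C APR-MAY" = 0)
  gp <- gen_passage(cfg, z, 1982, total = 100000L)
  expect_equal(sum(gp$counts$counts), 100000L)
  mean_day <- sum(seq_len(45) * gp$counts$counts) / gp$counts$total
  # day d covers (d-1, d], so a continuous mean of 22.5 maps to ~23.0
  expect_equal(mean_day, 23, tolerance = 0.1)
})

test_that("a +1 SD covariate shifts the realised mean by the injected effect", {
  cfg <- scenario_config(
    n_years = 5,
    cohorts = list(solo = list(weight = 1, base_mean_day = 20, sd_days = 5,
                               effects = c("A APR-MAY" = 2))),
    climate = list(list(name = "A APR-MAY", months = c(4, 5), lag_years = 0,
                        mean = 0, sd = 1, trend = 0, month_sd = 0.3)),
    mean_noise_sd = 0, seed = 9)
  g0 <- gen_passage(cfg, c("A APR-MAY" = 0), 1982, total = 100000L)
  g1 <- gen_passage(cfg, c("A APR-MAY" = 1), 1982, total = 100000L)
  m0 <- sum(seq_len(45) * g0$counts$counts) / 1e5
  m1 <- sum(seq_len(45) * g1$counts$counts) / 1e5
  expect_equal(m1 - m0, 2, tolerance = 0.1)
  expect_equal(g1$truth$cohort_means[["solo"]] -
                 g0$truth$cohort_means[["solo"]], 2, tolerance = 1e-12)
})

test_that("gen_study writes byte-identical files for the same config", {
  cfg <- small_cfg()
  d1 <- tempfile("synthA-"); d2 <- tempfile("synthB-")
  t1 <- gen_study(cfg, dir = d1)
  t2 <- gen_study(cfg, dir = d2)
  for (f in names(t1$files)) {
    expect_identical(readLines(t1$files[[f]]), readLines(t2$files[[f]]),
                     label = paste("file", f))
  }
})

test_that("recaptures deduplicate back to the drawn season totals", {
  cfg <- small_cfg(recapture_fraction = 0.2)
  truth <- gen_study(cfg)
  caps <- truth$captures
  caps$date <- as.Date(caps$date)
  class(caps) <- c("capture_records", "data.frame")
  win <- season_window("spring")
  for (y in c(2000L, 2005L)) {
    fc <- first_captures(caps, win, y)
    fc <- fc[fc$age_class == "full_grown", ]
    expect_equal(nrow(fc), unname(truth$totals[as.character(y)]))
    # duplicates existed before dedup
    in_win <- caps[!is.na(day_index(caps$date, win, y)) &
                     caps$age_class == "full_grown", ]
    expect_gt(nrow(in_win), nrow(fc))
  }
})

test_that("sub-threshold years fall to the season filter downstream", {
  cfg <- small_cfg()
  truth <- gen_study(cfg)
  caps <- truth$captures
  caps$date <- as.Date(caps$date)
  class(caps) <- c("capture_records", "data.frame")
  win <- season_window("spring")
  years <- 2000:2007
  counts <- lapply(years, function(y) {
    daily_counts(first_captures(caps, win, y), win, y)
  })
  flt <- filter_seasons(counts, 30)
  expect_true(2003L %in% flt$excluded_years)
})

test_that("the autumn outlier year is injected as configured", {
  cfg <- small_cfg()
  truth <- gen_study(cfg)
  caps <- truth$captures
  caps$date <- as.Date(caps$date)
  class(caps) <- c("capture_records", "data.frame")
  ei <- effort_index(caps, truth$effort)
  out_year <- cfg$autumn$outlier_year
  others <- ei$per50[ei$year != out_year]
  expect_gt(ei$per50[ei$year == out_year], 2.5 * mean(others))
})
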