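# Named substreams off a single root seed: draws for one (component, year)
# never depend on whether other years exist, so adding a year leaves
# earlier years' data untouched.  Simple multiplicative hash; collisions
# are harmless (streams only need to be decoupled, not cryptographic).
.substream <- function(root, ...) {
  parts <- list(...)
  h <- (as.double(root) %% 2147483647) + 1
  for (p in parts) {
    if (is.character(p)) {
      ints <- utf8ToInt(p)
      p <- sum(ints * seq_along(ints))
    }
    h <- (h * 48271 + as.double(p) + 7) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

.default_cohorts <- function() {
  list(
    early = list(weight = 0.32, base_mean_day = 13, sd_days = 5,
                 effects = c("SOI AUG-OCT_1y" = -2, "IOD AUG-OCT_1y" = -2,
                             "PSAH AUG-OCT_1y" = -1.5, "TSAH AUG-OCT_1y" = -1)),
    mid = list(weight = 0.36, base_mean_day = 25, sd_days = 5,
               effects = c("TLEB APR-MAY" = -2, "NAO APR-MAY" = -2,
                           "IOD AUG-OCT_1y" = -1, "SCAND JUN-JUL_1y" = -2)),
    late = list(weight = 0.32, base_mean_day = 36, sd_days = 4.5,
                effects = c("TLEB APR-MAY" = -1.5, "NAO NOV-MAR" = -1,
                            "PSAH NOV-MAR" = -1.5, "SCAND JUN-JUL_1y" = -1.5))
  )
}

.default_climate_specs <- function() {
  mk <- function(name, months, lag, trend = 0) {
    list(name = name, months = months, lag_years = lag,
         mean = 0, sd = 1, trend = trend, month_sd = 0.3)
  }
  # upward trends on the Sahel autumn indices and local spring temperature
  # mirror the secular warming/wetting the stated world assumes
  list(
    mk("TLEB APR-MAY", c(4, 5), 0, trend = 0.04),
    mk("NAO APR-MAY", c(4, 5), 0),
    mk("NAO NOV-MAR", c(11, 12, 1, 2, 3), 0),
    mk("PSAH NOV-MAR", c(11, 12, 1, 2, 3), 0),
    mk("PSAH AUG-OCT_1y", c(8, 9, 10), 1, trend = 0.03),
    mk("TSAH AUG-OCT_1y", c(8, 9, 10), 1, trend = 0.03),
    mk("IOD AUG-OCT_1y", c(8, 9, 10), 1),
    mk("SOI AUG-OCT_1y", c(8, 9, 10), 1),
    mk("SCAND JUN-JUL_1y", c(6, 7), 1)
  )
}

#' Synthetic-study scenario configuration
#'
#' Describes the stated world the generator emulates: a fixed spring
#' window, a mixture of migratory cohorts whose mean transit dates
#' respond linearly (days per standard deviation) to standardised
#' seasonal climate covariates, negative-binomial season totals, a
#' couple of deliberately sub-threshold springs, within-season
#' recaptures, and an autumn juvenile series with varying net effort and
#' one outlier autumn.  Defaults mirror the study scale: 36 years from
#' 1982, a 45-day window, roughly 30-600 birds per spring, nine climate
#' covariates, and negative climate effects (higher index, earlier
#' passage).
#'
#' @param n_years number of spring seasons (>= 5).
#' @param start_year first spring year.
#' @param window a [season_window()] (default spring).
#' @param cohorts list of cohorts, each `list(weight, base_mean_day,
#'   sd_days, effects)` with `effects` a named vector of days per SD of
#'   the named climate variable; weights must sum to 1.
#' @param season_total `list(mu, size)` for negative-binomial totals.
#' @param sub_threshold_years springs forced below the 30-bird filter.
#' @param recapture_fraction fraction of birds recaptured later in the
#'   same season (exercises deduplication).
#' @param mean_noise_sd year-to-year jitter (days) on each cohort mean.
#' @param trend optional per-cohort drift, days per year.
#' @param climate list of per-variable generator specs `list(name,
#'   months, lag_years, mean, sd, trend, month_sd)`.
#' @param autumn autumn-series spec: `juv_mu`, `juv_size`, `adult_frac`,
#'   `nets_range`, `outlier_year`, `outlier_factor`.
#' @param n_recoveries,speed direct-recovery count and per-pair speed
#'   distribution `list(mean, sd)` in km/day.
#' @param seed root seed; all randomness flows from it via named
#'   substreams.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 36L, start_year = 1982L,
                            window = season_window("spring"),
                            cohorts = .default_cohorts(),
                            season_total = list(mu = 230, size = 6),
                            sub_threshold_years = start_year + c(11L, 29L),
                            recapture_fraction = 0.15,
                            mean_noise_sd = 1,
                            trend = NULL,
                            climate = .default_climate_specs(),
                            autumn = list(juv_mu = 600, juv_size = 5,
                                          adult_frac = 0.25,
                                          nets_range = c(38L, 76L),
                                          outlier_year = start_year,
                                          outlier_factor = 5),
                            n_recoveries = 25L,
                            speed = list(mean = 66, sd = 8),
                            seed = 1L) {
  if (n_years < 5) stop("n_years must be >= 5")
  w <- vapply(cohorts, function(co) co$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("cohort weights must sum to 1")
  if (any(vapply(cohorts, function(co) co$sd_days, numeric(1)) <= 0)) {
    stop("cohort sd_days must be positive")
  }
  cfg <- list(n_years = as.integer(n_years),
              start_year = as.integer(start_year), window = window,
              cohorts = cohorts, season_total = season_total,
              sub_threshold_years = as.integer(sub_threshold_years),
              recapture_fraction = recapture_fraction,
              mean_noise_sd = mean_noise_sd, trend = trend,
              climate = climate, autumn = autumn,
              n_recoveries = as.integer(n_recoveries), speed = speed,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate monthly climate series with known seasonal-mean structure
#'
#' For each configured variable the per-year seasonal mean is drawn as
#' `mean + trend * (year - start_year) + N(0, sd)`; monthly values are
#' that seasonal value plus centred within-window noise (`month_sd`), so
#' the seasonal mean recovered through [seasonal_mean()] equals the drawn
#' value exactly.  Variables are mutually independent.  Each variable is
#' emitted under its own index name, with months covering the window
#' (including lagged calendar years).
#'
#' @param config a [scenario_config()].
#' @param seed root seed (default `config$seed`).
#' @return list: `monthly` (a `climate_series` data frame), `seasonal`
#'   (years x variables matrix of the exact seasonal means), `roster`
#'   (roster data frame usable with [build_covariates()]).
#' @export
gen_climate <- function(config, seed = config$seed) {
  years <- config$start_year + seq_len(config$n_years) - 1L
  specs <- config$climate
  nm <- vapply(specs, function(s) s$name, character(1))
  seasonal <- matrix(NA_real_, length(years), length(specs),
                     dimnames = list(years, nm))
  rows <- list()
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    k <- length(sp$months)
    for (i in seq_along(years)) {
      y <- years[i]
      set.seed(.substream(seed, "climate", sp$name, y))
      s <- sp$mean + sp$trend * (y - config$start_year) +
        stats::rnorm(1, 0, sp$sd)
      dev <- stats::rnorm(k, 0, sp$month_sd)
      dev <- dev - mean(dev)
      cal_years <- .month_years(sp$months, y, sp$lag_years)
      seasonal[i, j] <- s
      rows[[length(rows) + 1]] <- data.frame(
        index = sp$name, year = cal_years, month = as.integer(sp$months),
        value = s + dev, stringsAsFactors = FALSE)
    }
  }
  monthly <- do.call(rbind, rows)
  monthly <- unique(monthly[order(monthly$index, monthly$year, monthly$month), ])
  rownames(monthly) <- NULL
  class(monthly) <- c("climate_series", "data.frame")
  roster <- data.frame(
    no = seq_along(specs), name = nm, index = nm,
    months = vapply(specs, function(s) paste(s$months, collapse = ","),
                    character(1)),
    lag_years = vapply(specs, function(s) as.integer(s$lag_years), integer(1)),
    selected = TRUE, stringsAsFactors = FALSE)
  list(monthly = monthly, seasonal = seasonal, roster = roster)
}

# Expected daily passage density: weighted mixture of day-discretised
# Gaussians truncated and renormalised to the window.  Day d covers
# (d-1, d].
.passage_density <- function(means, sds, weights, n_days,
                             max_truncation = 0.25) {
  p <- numeric(n_days)
  for (c in seq_along(means)) {
    cdf <- stats::pnorm(0:n_days, means[c], sds[c])
    mass <- diff(cdf)
    inside <- cdf[n_days + 1] - cdf[1]
    if (1 - inside > max_truncation) {
      warning(sprintf(
        "cohort %d: %.0f%% of passage mass falls outside the window",
        c, 100 * (1 - inside)))
    }
    p <- p + weights[c] * mass / inside
  }
  p / sum(p)
}

#' Generate one spring season of daily counts
#'
#' Per-cohort mean day = `base_mean_day + sum(effects * z) + trend *
#' (year index) + N(0, mean_noise_sd)`; daily counts are a multinomial
#' draw of the season total from the truncated-Gaussian mixture density.
#'
#' @param config a [scenario_config()].
#' @param z named numeric vector: the year's standardised climate
#'   covariates (names must cover every effect name).
#' @param year spring year.
#' @param total season total; drawn negative-binomially when `NULL`.
#' @param seed root seed (default `config$seed`).
#' @return list: `counts` (a `season_counts`), `truth` (list with
#'   `cohort_means`, `total`, `density`).
#' @export
gen_passage <- function(config, z, year, total = NULL, seed = config$seed) {
  nd <- config$window$n_days
  co <- config$cohorts
  t_idx <- year - config$start_year
  means <- sds <- wts <- numeric(length(co))
  for (i in seq_along(co)) {
    eff <- co[[i]]$effects
    missing_z <- setdiff(names(eff), names(z))
    if (length(missing_z)) {
      stop("covariates missing for effects: ",
           paste(missing_z, collapse = ", "))
    }
    set.seed(.substream(seed, "cohort_noise", names(co)[i], year))
    drift <- if (!is.null(config$trend)) config$trend[[i]] * t_idx else 0
    means[i] <- co[[i]]$base_mean_day + sum(eff * z[names(eff)]) + drift +
      stats::rnorm(1, 0, config$mean_noise_sd)
    sds[i] <- co[[i]]$sd_days
    wts[i] <- co[[i]]$weight
  }
  dens <- .passage_density(means, sds, wts, nd)
  if (is.null(total)) {
    set.seed(.substream(seed, "total", year))
    total <- max(1L, stats::rnbinom(1, mu = config$season_total$mu,
                                    size = config$season_total$size))
  }
  set.seed(.substream(seed, "multinomial", year))
  counts <- as.integer(stats::rmultinom(1, total, dens))
  sc <- structure(list(year = as.integer(year), window = config$window,
                       counts = counts,
                       dates = window_dates(config$window, year),
                       total = as.integer(total)),
                  class = "season_counts")
  list(counts = sc,
       truth = list(cohort_means = stats::setNames(means, names(co)),
                    total = as.integer(total), density = dens))
}

#' Generate a complete synthetic study
#'
#' Produces everything the pipeline reads: a capture table (spring
#' full-grown birds including within-season recaptures, plus autumn
#' juveniles and adults), a per-season net-effort table, monthly climate
#' CSV-ready series with their roster, direct-recovery pairs, and a
#' truth bundle recording the injected cohort means, seasonal climate
#' values and totals for recovery assertions.  Writing the files and
#' rerunning with the same config and seed is byte-identical.
#'
#' @param config a [scenario_config()].
#' @param dir optional directory; when given, writes `captures.csv`,
#'   `effort.csv`, `climate.csv`, `roster.csv`, `recoveries.csv` and
#'   `truth.tsv` there.
#' @return (Invisibly when writing) the truth bundle: list with
#'   `config`, `captures`, `effort`, `climate`, `roster`, `recoveries`,
#'   `seasonal`, `z`, `cohort_means`, `totals`, `files`.
#' @export
gen_study <- function(config, dir = NULL) {
  seed <- config$seed
  years <- config$start_year + seq_len(config$n_years) - 1L
  clim <- gen_climate(config, seed)
  z <- apply(clim$seasonal, 2, standardize)
  rownames(z) <- rownames(clim$seasonal)

  cap_rows <- list()
  cohort_means <- matrix(NA_real_, length(years), length(config$cohorts),
                         dimnames = list(years, names(config$cohorts)))
  totals <- stats::setNames(integer(length(years)), years)
  for (i in seq_along(years)) {
    y <- years[i]
    total <- NULL
    if (y %in% config$sub_threshold_years) {
      set.seed(.substream(seed, "sub_threshold", y))
      total <- sample(8:25, 1)
    }
    gp <- gen_passage(config, z[as.character(y), ], y, total = total,
                      seed = seed)
    cohort_means[i, ] <- gp$truth$cohort_means
    totals[i] <- gp$truth$total
    day_of_bird <- rep(seq_len(config$window$n_days), gp$counts$counts)
    n <- length(day_of_bird)
    if (n == 0) next
    ids <- sprintf("S%d-%04d", y, seq_len(n))
    dates <- gp$counts$dates[day_of_bird]
    cap_rows[[length(cap_rows) + 1]] <- data.frame(
      ring_id = ids, date = format(dates), age_class = "full_grown",
      site = "SYNTH", stringsAsFactors = FALSE)
    # within-season recaptures: a later second row for a sampled subset
    set.seed(.substream(seed, "recapture", y))
    elig <- which(day_of_bird < config$window$n_days)
    nr <- round(config$recapture_fraction * n)
    if (nr > 0 && length(elig)) {
      pick <- sample(elig, min(nr, length(elig)))
      gap <- vapply(day_of_bird[pick], function(d) {
        sample(seq_len(config$window$n_days - d), 1)
      }, integer(1))
      cap_rows[[length(cap_rows) + 1]] <- data.frame(
        ring_id = ids[pick],
        date = format(gp$counts$dates[day_of_bird[pick] + gap]),
        age_class = "full_grown", site = "SYNTH", stringsAsFactors = FALSE)
    }
  }

  # autumn juveniles (and adults, which the effort index must ignore)
  aut_win <- season_window("autumn")
  aut_years <- (config$start_year - 1L):(config$start_year + config$n_years - 2L)
  eff_rows <- list()
  for (ay in aut_years) {
    set.seed(.substream(seed, "autumn", ay))
    nets <- sample(config$autumn$nets_range[1]:config$autumn$nets_range[2], 1)
    nj <- stats::rnbinom(1, mu = config$autumn$juv_mu,
                         size = config$autumn$juv_size)
    nj <- max(20L, nj)
    if (ay == config$autumn$outlier_year) {
      nj <- as.integer(nj * config$autumn$outlier_factor)
    }
    na <- as.integer(round(config$autumn$adult_frac * nj))
    adates <- window_dates(aut_win, ay)
    jd <- sample(seq_len(aut_win$n_days), nj, replace = TRUE,
                 prob = stats::dnorm(seq_len(aut_win$n_days), 35, 14))
    ad <- sample(seq_len(aut_win$n_days), na, replace = TRUE)
    cap_rows[[length(cap_rows) + 1]] <- data.frame(
      ring_id = c(sprintf("A%d-%05d", ay, seq_len(nj)),
                  sprintf("B%d-%05d", ay, seq_len(na))),
      date = format(adates[c(jd, ad)]),
      age_class = c(rep("juvenile", nj), rep("adult", na)),
      site = "SYNTH", stringsAsFactors = FALSE)
    eff_rows[[length(eff_rows) + 1]] <- data.frame(
      year = ay, season = "autumn", nets = nets, stringsAsFactors = FALSE)
  }
  for (y in years) {
    set.seed(.substream(seed, "spring_nets", y))
    eff_rows[[length(eff_rows) + 1]] <- data.frame(
      year = y, season = "spring", nets = sample(35:57, 1),
      stringsAsFactors = FALSE)
  }

  captures <- do.call(rbind, cap_rows)
  captures <- captures[order(captures$date, captures$ring_id), ]
  rownames(captures) <- NULL
  effort <- do.call(rbind, eff_rows)
  effort <- effort[order(effort$season, effort$year), ]
  rownames(effort) <- NULL

  set.seed(.substream(seed, "recoveries"))
  elapsed <- sample(1:5, config$n_recoveries, replace = TRUE)
  spd <- stats::rnorm(config$n_recoveries, config$speed$mean, config$speed$sd)
  ry <- sample(years, config$n_recoveries, replace = TRUE)
  rd <- .window_start(config$window, 2000) +
    sample(0:(config$window$n_days - 6), config$n_recoveries, replace = TRUE)
  rd <- as.Date(sprintf("%d-%s", ry, format(rd, "%m-%d")))
  recoveries <- data.frame(
    ring_date = format(rd), find_date = format(rd + elapsed),
    distance_km = round(spd * elapsed, 1), stringsAsFactors = FALSE)

  truth <- list(config = config, captures = captures, effort = effort,
                climate = clim$monthly, roster = clim$roster,
                recoveries = recoveries, seasonal = clim$seasonal, z = z,
                cohort_means = cohort_means, totals = totals,
                expected_excluded = intersect(config$sub_threshold_years,
                                              years))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(captures = file.path(dir, "captures.csv"),
               effort = file.path(dir, "effort.csv"),
               climate = file.path(dir, "climate.csv"),
               roster = file.path(dir, "roster.csv"),
               recoveries = file.path(dir, "recoveries.csv"),
               truth = file.path(dir, "truth.tsv"))
    utils::write.csv(captures, files["captures"], row.names = FALSE)
    utils::write.csv(effort, files["effort"], row.names = FALSE)
    utils::write.csv(truth$climate, files["climate"], row.names = FALSE)
    utils::write.csv(truth$roster, files["roster"], row.names = FALSE)
    utils::write.csv(recoveries, files["recoveries"], row.names = FALSE)
    write_truth(truth, files["truth"])
    truth$files <- files
    return(invisible(truth))
  }
  truth
}

#' Serialise the truth bundle as plain-text key-value lines
#'
#' @param truth a truth bundle from [gen_study()].
#' @param path output path (TSV: key, value).
#' @export
write_truth <- function(truth, path) {
  kv <- c(
    sprintf("seed\t%d", truth$config$seed),
    sprintf("n_years\t%d", truth$config$n_years),
    sprintf("start_year\t%d", truth$config$start_year),
    sprintf("total.%s\t%d", names(truth$totals), truth$totals),
    unlist(lapply(rownames(truth$cohort_means), function(y) {
      sprintf("cohort_mean.%s.%s\t%.6f", y, colnames(truth$cohort_means),
              truth$cohort_means[y, ])
    })),
    unlist(lapply(rownames(truth$seasonal), function(y) {
      sprintf("seasonal.%s.%s\t%.6f", y, colnames(truth$seasonal),
              truth$seasonal[y, ])
    }))
  )
  writeLines(kv, path)
}
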