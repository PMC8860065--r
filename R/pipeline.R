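# Polynomial rolling hash of a string, 13 hex digits; stamps outputs so
# two runs with equal configs are identifiable (and byte-identical).
# Moduli keep intermediate products inside exact double arithmetic.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 33554393
    h2 <- (h2 * 37 + b) %% 16777213
  }
  sprintf("%07x%06x", as.integer(h1), as.integer(h2))
}

.write_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_effort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("year", "season", "nets")
  if (!all(need %in% names(df))) {
    stop("effort file must have columns: ", paste(need, collapse = ", "))
  }
  df$year <- as.integer(df$year); df$nets <- as.integer(df$nets)
  df
}

#' Pipeline run configuration
#'
#' Bundles input paths and analysis parameters; the FNV-1a hash of its
#' serialised form stamps every output file so a run is reproducible
#' from its config.
#'
#' @param captures,effort,climate,roster,recoveries input file paths
#'   (`roster` and `recoveries` optional; roster defaults to
#'   [climate_roster()]).
#' @param out_dir output directory for CSV artifacts.
#' @param min_total season-inclusion threshold (default 30).
#' @param delta_aicc top-model cutoff (default 2).
#' @param r_threshold collinearity screen threshold (default 0.7).
#' @param sign_flip flip the anomaly sign convention (default `FALSE`:
#'   positive = later than baseline).
#' @param exclude_autumn_years outlier autumns dropped from the juvenile
#'   regressions.
#' @param candidates optional restriction of the model-selection
#'   candidate set (default: all roster variables plus `"Year"`).
#' @param seed integer seed recorded in the stamp.
#' @return An object of class `run_config`.
#' @export
run_config <- function(captures, effort, climate, roster = NULL,
                       recoveries = NULL, out_dir = tempfile("springAA-"),
                       min_total = 30L, delta_aicc = 2, r_threshold = 0.7,
                       sign_flip = FALSE, exclude_autumn_years = integer(0),
                       candidates = NULL, seed = 1L) {
  cfg <- list(captures = captures, effort = effort, climate = climate,
              roster = roster, recoveries = recoveries, out_dir = out_dir,
              min_total = as.integer(min_total), delta_aicc = delta_aicc,
              r_threshold = r_threshold, sign_flip = sign_flip,
              exclude_autumn_years = as.integer(exclude_autumn_years),
              candidates = candidates, seed = as.integer(seed))
  stamp <- cfg[setdiff(names(cfg), "out_dir")]
  cfg$hash <- .fnv1a(as.character(jsonlite::toJSON(stamp, auto_unbox = TRUE,
                                                   digits = NA)))
  class(cfg) <- "run_config"
  cfg
}

.all_period_spec <- function(baseline) {
  aa <- build_periods(baseline,
                      data.frame(label = "AA", pct_lo = 0L, pct_hi = 100L,
                                 stringsAsFactors = FALSE))
  rbind(aa,
        build_periods(baseline, main_period_ranges(), contiguous = TRUE),
        build_periods(baseline, sub_period_ranges()))
}

#' Run the anomaly stage: counts, baseline, periods, anomaly tables
#'
#' Reads captures and effort, deduplicates to first capture per season,
#' tallies daily counts over the spring window, applies the season
#' filter, builds the multiyear baseline and the percentile-defined
#' periods (overall AA, main periods MP1-MP3, sub-periods SP1-SP9), and
#' decomposes each included year's anomaly.  Writes stamped CSVs
#' (`baseline.csv`, `periods.csv`, `anomalies.csv`, `season_totals.csv`,
#' `effort_index.csv`) to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return list: `baseline`, `periods`, `anomalies` (long data frame),
#'   `included_years`, `excluded_years`, `effort_index`, `files`.
#' @export
run_anomaly <- function(config) {
  caps <- load_captures(config$captures)
  effort <- .read_effort(config$effort)
  win <- season_window("spring")
  spring_years <- sort(unique(as.integer(format(caps$date, "%Y"))))
  all_counts <- lapply(spring_years, function(y) {
    daily_counts(first_captures(caps, win, y), win, y)
  })
  all_counts <- all_counts[vapply(all_counts, function(s) s$total, integer(1)) > 0]
  flt <- filter_seasons(all_counts, config$min_total)
  if (length(flt$included) < 2) stop("fewer than 2 seasons pass the filter")
  curves <- lapply(flt$included, cumulative_percent)
  years <- vapply(flt$included, function(s) s$year, integer(1))
  names(curves) <- years
  baseline <- multiyear_baseline(curves)
  periods <- .all_period_spec(baseline)
  anomalies <- anomaly_table(curves, baseline, periods,
                             sign_flip = config$sign_flip)
  eff_idx <- effort_index(caps, effort)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- format(window_dates(win, 2001), "%m-%d")
  files <- c(
    baseline = .write_csv(
      data.frame(day_index = seq_along(baseline), date = md,
                 cumulative_pct = as.numeric(baseline)),
      file.path(config$out_dir, "baseline.csv"), config$hash),
    periods = .write_csv(as.data.frame(periods),
                         file.path(config$out_dir, "periods.csv"),
                         config$hash),
    anomalies = .write_csv(anomalies,
                           file.path(config$out_dir, "anomalies.csv"),
                           config$hash),
    season_totals = .write_csv(
      data.frame(year = vapply(all_counts, function(s) s$year, integer(1)),
                 total = vapply(all_counts, function(s) s$total, integer(1)),
                 included = vapply(all_counts, function(s) s$total,
                                   integer(1)) >= config$min_total),
      file.path(config$out_dir, "season_totals.csv"), config$hash),
    effort_index = .write_csv(eff_idx,
                              file.path(config$out_dir, "effort_index.csv"),
                              config$hash))
  message(sprintf("anomaly stage: %d seasons included, %d excluded (%s)",
                  length(years), length(flt$excluded_years),
                  paste(flt$excluded_years, collapse = ", ")))
  list(baseline = baseline, periods = periods, anomalies = anomalies,
       included_years = years, excluded_years = flt$excluded_years,
       curves = curves, effort_index = eff_idx, files = files)
}

.aa_series <- function(anomalies, period) {
  sub <- anomalies[anomalies$period == period, ]
  stats::setNames(sub$aa_days, sub$year)
}

#' Run the modelling stage: selection, trends, profile, juveniles
#'
#' Builds the standardised climate covariates, runs all-subsets AICc
#' selection for the overall anomaly and the three main periods (with
#' `Year` always a candidate), extracts top-model sets and
#' contributions, screens collinear pairs, fits the moving-window
#' partial-correlation profile of the nine sub-periods on the selected
#' variables, tests year trends with Benjamini-Hochberg correction, and
#' regresses the spring anomalies on the previous autumn's
#' effort-normalised juvenile index (square-root scale).  Years missing
#' any covariate are dropped listwise with a message.
#'
#' @param config a [run_config()].
#' @param anomaly optional result of [run_anomaly()] (recomputed when
#'   `NULL`).
#' @return list: `best` (named list of best `regression_fit`s),
#'   `rankings`, `contributions`, `selected`, `profile`, `trends`,
#'   `juvenile`, `files`.
#' @export
run_models <- function(config, anomaly = NULL) {
  if (is.null(anomaly)) anomaly <- run_anomaly(config)
  climate <- read_climate(config$climate)
  roster <- if (is.null(config$roster)) climate_roster() else {
    r <- utils::read.csv(config$roster, stringsAsFactors = FALSE,
                         comment.char = "#")
    r$selected <- as.logical(r$selected)
    r
  }
  years <- anomaly$included_years
  ok <- vapply(years, function(y) {
    !inherits(tryCatch(
      build_covariates(climate, roster, y), error = function(e) e),
      "error")
  }, logical(1))
  if (any(!ok)) {
    message("dropping ", sum(!ok), " year(s) missing covariates: ",
            paste(years[!ok], collapse = ", "))
  }
  years <- years[ok]
  Xraw <- build_covariates(climate, roster, years)
  Xraw <- cbind(Xraw, Year = years - min(years) + 1)
  candidates <- if (is.null(config$candidates)) colnames(Xraw) else
    config$candidates
  yk <- as.character(years)

  responses <- c("AA", "MP1", "MP2", "MP3")
  rankings <- best <- tops <- list()
  contribs <- list()
  for (resp in responses) {
    y_raw <- .aa_series(anomaly$anomalies, resp)[yk]
    ys <- standardize(y_raw)
    Xs <- standardize_matrix(Xraw[yk, , drop = FALSE])
    rk <- all_subsets(ys, Xs, candidates)
    tp <- top_models(rk, config$delta_aicc, response = resp)
    rankings[[resp]] <- rk
    tops[[resp]] <- tp
    best[[resp]] <- tp[[1]]
    contribs[[resp]] <- contribution_table(tp, candidates)
  }
  contrib_mat <- do.call(rbind, contribs)

  # variables for the profile: the roster's selected nine by default,
  # screened for collinearity using their best contribution across the
  # main-period top sets
  sel_names <- roster$name[roster$selected]
  max_contrib <- stats::setNames(rep(0, length(sel_names)), sel_names)
  shared <- intersect(sel_names, colnames(contrib_mat))
  max_contrib[shared] <- apply(contrib_mat[, shared, drop = FALSE], 2, max)
  Xsel <- Xraw[yk, sel_names, drop = FALSE]
  selected <- collinearity_screen(Xsel, max_contrib,
                                  r_threshold = config$r_threshold,
                                  priority = sel_names)
  sub_aa <- lapply(stats::setNames(paste0("SP", 1:9), paste0("SP", 1:9)),
                   function(p) .aa_series(anomaly$anomalies, p)[yk])
  profile <- window_profile(sub_aa, Xraw[yk, selected, drop = FALSE])

  trend_series <- lapply(stats::setNames(responses, responses),
                         function(p) .aa_series(anomaly$anomalies, p)[yk])
  trends <- trend_with_bh(trend_series)

  juv <- NULL
  if (!is.null(anomaly$effort_index) && nrow(anomaly$effort_index)) {
    per50 <- stats::setNames(anomaly$effort_index$per50,
                             anomaly$effort_index$year)
    jrows <- lapply(responses, function(p) {
      r <- juvenile_regression(.aa_series(anomaly$anomalies, p), per50,
                               exclude_years = config$exclude_autumn_years)
      data.frame(period = p, n = r$n, slope = r$slope, r2 = r$r2,
                 p_raw = r$p, stringsAsFactors = FALSE)
    })
    juv <- do.call(rbind, jrows)
    juv$p_bh <- bh_adjust(juv$p_raw)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (resp in responses) {
    files[paste0("selection_", resp)] <- .write_csv(
      utils::head(rankings[[resp]]$table, 200),
      file.path(config$out_dir, sprintf("model_selection_%s.csv", resp)),
      config$hash)
    bt <- coef_table(best[[resp]])
    if (!nrow(bt)) {
      bt <- data.frame(predictor = "(intercept only)", Estimate = NA_real_,
                       SE = NA_real_, t = NA_real_, p = NA_real_,
                       VIF = NA_real_, R2 = NA_real_, pR = NA_real_,
                       stringsAsFactors = FALSE)
    }
    bt <- cbind(response = resp, bt, n = best[[resp]]$n,
                adj_r2 = best[[resp]]$adj_r2)
    files[paste0("best_", resp)] <- .write_csv(
      bt, file.path(config$out_dir, sprintf("best_model_%s.csv", resp)),
      config$hash)
  }
  files["contributions"] <- .write_csv(
    data.frame(variable = colnames(contrib_mat),
               t(contrib_mat), check.names = FALSE),
    file.path(config$out_dir, "contributions.csv"), config$hash)
  files["profile"] <- .write_csv(profile$long,
                                 file.path(config$out_dir, "profile.csv"),
                                 config$hash)
  files["trends"] <- .write_csv(trends,
                                file.path(config$out_dir, "trends.csv"),
                                config$hash)
  if (!is.null(juv)) {
    files["juvenile"] <- .write_csv(juv,
                                    file.path(config$out_dir, "juvenile.csv"),
                                    config$hash)
  }
  list(best = best, tops = tops, rankings = rankings,
       contributions = contrib_mat, selected = selected, profile = profile,
       trends = trends, juvenile = juv, years = years, files = files)
}
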