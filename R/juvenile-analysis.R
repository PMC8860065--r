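#' Great-circle distance (haversine), in kilometres
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @param radius_km spherical-earth radius (default 6371 km).
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Read direct ringing recoveries
#'
#' A direct recovery is a marked bird re-encountered within the same
#' migration episode; displacement over elapsed time estimates migration
#' speed.  The CSV needs `ring_date` and `find_date` (ISO 8601) plus
#' either `distance_km` or the two coordinate pairs `ring_lat`,
#' `ring_lon`, `find_lat`, `find_lon` (decimal degrees; distance then
#' computed on a spherical earth).  Elapsed times shorter than one day
#' round up to 1 day.
#'
#' @param path CSV path.
#' @return data frame of class `recovery_pairs` with `ring_date`,
#'   `find_date`, `distance_km`, `elapsed_days`, `speed_kmd`.
#' @export
read_recoveries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("ring_date", "find_date") %in% names(df))) {
    stop("recoveries need ring_date and find_date columns")
  }
  ring <- as.Date(df$ring_date); find <- as.Date(df$find_date)
  if (anyNA(ring) || anyNA(find)) stop("unparseable recovery date(s)")
  if (!"distance_km" %in% names(df)) {
    coords <- c("ring_lat", "ring_lon", "find_lat", "find_lon")
    if (!all(coords %in% names(df))) {
      stop("recoveries need distance_km or coordinate columns: ",
           paste(coords, collapse = ", "))
    }
    df$distance_km <- haversine_km(df$ring_lat, df$ring_lon,
                                   df$find_lat, df$find_lon)
  }
  elapsed <- as.numeric(find - ring)
  if (any(elapsed <= 0)) {
    stop("find_date must be after ring_date (rows: ",
         paste(which(elapsed <= 0), collapse = ", "), ")")
  }
  elapsed <- pmax(1, ceiling(elapsed))
  out <- data.frame(ring_date = ring, find_date = find,
                    distance_km = df$distance_km,
                    elapsed_days = as.integer(elapsed),
                    speed_kmd = df$distance_km / elapsed)
  class(out) <- c("recovery_pairs", "data.frame")
  out
}

#' Mean migration speed from direct recoveries
#'
#' @param pairs a `recovery_pairs` data frame (or any data frame with a
#'   `speed_kmd` column).
#' @return Mean of the per-pair speeds, km/day.
#' @export
mean_migration_speed <- function(pairs) {
  if (!nrow(pairs)) stop("no recovery pairs")
  mean(pairs$speed_kmd)
}

#' Regress a spring anomaly on the previous autumn's juvenile index
#'
#' Pairs the anomaly of spring year `y` with the effort-normalised count
#' of juveniles (per 50 nets) of autumn `y - 1`, drops configured outlier
#' autumns, applies a square-root transform to the (right-skewed) index,
#' and fits a simple linear regression.  A positive slope means later
#' passage after more productive autumns.  The outlier exclusion is a
#' judgment call supplied by the caller, not an automated rule.
#'
#' @param aa numeric anomaly vector named by spring year.
#' @param njuv_prev numeric per-50-nets juvenile index named by autumn
#'   year.
#' @param exclude_years autumn years to drop before pairing.
#' @return list: `n`, `years`, `slope`, `intercept`, `r2`, `p`.
#' @export
juvenile_regression <- function(aa, njuv_prev, exclude_years = integer(0)) {
  yrs <- as.integer(names(aa))
  prev <- yrs - 1L
  ok <- as.character(prev) %in% names(njuv_prev) & !(prev %in% exclude_years)
  yrs <- yrs[ok]
  if (length(yrs) < 3) stop("fewer than 3 paired years after exclusions")
  x <- sqrt(njuv_prev[as.character(yrs - 1L)])
  y <- aa[as.character(yrs)]
  if (stats::sd(x) < 1e-12) stop("zero-variance predictor (juvenile index)")
  Xd <- cbind(1, as.numeric(x))
  eng <- .ols_engine(as.numeric(y), Xd)
  tval <- eng$coef[2] / eng$se[2]
  list(n = length(yrs), years = yrs,
       slope = unname(eng$coef[2]), intercept = unname(eng$coef[1]),
       r2 = eng$r2,
       p = unname(2 * stats::pt(-abs(tval), eng$df_res)))
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' When both vectors are named, they are aligned on shared names first.
#'
#' @param x,y numeric vectors (optionally named, e.g. by year).
#' @return list: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  n <- length(x)
  if (n < 3) stop("need >= 3 paired values")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}
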