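#' Read a monthly climate-index table
#'
#' @param path CSV with columns `index`, `year`, `month`, `value` (one row
#'   per index-month; months 1..12, at most one value per (index, year,
#'   month)).
#' @return data frame of class `climate_series`.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("index", "year", "month", "value")
  if (!all(need %in% names(df))) {
    stop("climate file must have columns: ", paste(need, collapse = ", "))
  }
  df$year <- as.integer(df$year); df$month <- as.integer(df$month)
  df$value <- as.numeric(df$value)
  if (any(df$month < 1 | df$month > 12)) stop("months must be in 1..12")
  if (anyDuplicated(df[c("index", "year", "month")])) {
    stop("duplicate (index, year, month) rows in ", path)
  }
  class(df) <- c("climate_series", "data.frame")
  df
}

# Calendar-year offsets for a chronological month sequence: months after a
# wrap (e.g. Jan after Dec in Nov-Mar) belong to a later calendar year; the
# final month of the window lies in calendar year (year - lag_years).
.month_years <- function(months, year, lag_years) {
  off <- integer(length(months))
  for (i in seq_along(months)[-1]) {
    off[i] <- off[i - 1] + as.integer(months[i] < months[i - 1])
  }
  year - lag_years - (off[length(off)] - off)
}

#' Seasonal mean of a monthly climate index
#'
#' Arithmetic mean of the index over a window of months, for one target
#' (spring) year.  `months` is given in chronological order and may wrap
#' the year boundary: the Nov--Mar window for year `y` spans Nov--Dec of
#' `y - 1` and Jan--Mar of `y`.  `lag_years = 1` (the `"_1y"` suffix in
#' variable names) shifts the whole window one calendar year back, e.g.
#' Aug--Oct of the previous year.
#'
#' @param series a `climate_series` data frame, or any data frame with
#'   `year`, `month`, `value` (single index; pass `index` to select one).
#' @param months integer vector of months in chronological window order.
#' @param lag_years 0 or 1.
#' @param year target year (the year of the spring being modelled).
#' @param index optional index name to filter `series` by.
#' @return The mean of the monthly values; error naming any missing month.
#' @export
seasonal_mean <- function(series, months, lag_years = 0L, year, index = NULL) {
  if (!is.null(index)) series <- series[series$index == index, , drop = FALSE]
  yrs <- .month_years(months, year, lag_years)
  vals <- numeric(length(months))
  for (i in seq_along(months)) {
    hit <- series$year == yrs[i] & series$month == months[i]
    if (sum(hit) != 1) {
      stop("missing climate value: ",
           if (!is.null(index)) paste0(index, " ") else "",
           "year ", yrs[i], " month ", months[i])
    }
    vals[i] <- series$value[hit]
  }
  mean(vals)
}

#' The default climate-variable roster
#'
#' Fifteen seasonal-mean covariates built from seven monthly indices
#' (local coastal temperature TLEB, North Atlantic Oscillation NAO,
#' Scandinavian index SCAND, Sahel precipitation PSAH, Sahel temperature
#' anomaly TSAH, Indian Ocean Dipole IOD, Southern Oscillation Index SOI)
#' over the windows matching the migrant's annual cycle: Apr--May (spring
#' passage), Nov--Mar (wintering), Aug--Oct of the previous year (autumn
#' passage), Jun--Jul of the previous year (breeding).  The `selected`
#' column flags the nine variables retained for the moving-window
#' profile.  Negative monthly TSAH values indicate high Sahel
#' temperatures; values are passed through untransformed.
#'
#' @return data frame: `no`, `name`, `index`, `months` (comma string),
#'   `lag_years`, `selected`.
#' @export
climate_roster <- function() {
  df <- data.frame(
    no = 1:15,
    name = c("TLEB APR-MAY", "NAO APR-MAY", "SCAND APR-MAY",
             "NAO NOV-MAR", "PSAH NOV-MAR", "TSAH NOV-MAR",
             "IOD NOV-MAR", "SOI NOV-MAR",
             "NAO AUG-OCT_1y", "PSAH AUG-OCT_1y", "TSAH AUG-OCT_1y",
             "IOD AUG-OCT_1y", "SOI AUG-OCT_1y",
             "NAO JUN-JUL_1y", "SCAND JUN-JUL_1y"),
    index = c("TLEB", "NAO", "SCAND",
              "NAO", "PSAH", "TSAH", "IOD", "SOI",
              "NAO", "PSAH", "TSAH", "IOD", "SOI",
              "NAO", "SCAND"),
    months = c("4,5", "4,5", "4,5",
               rep("11,12,1,2,3", 5),
               rep("8,9,10", 5),
               "6,7", "6,7"),
    lag_years = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                  1L, 1L, 1L, 1L, 1L, 1L, 1L),
    selected = c(TRUE, TRUE, FALSE,
                 TRUE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, TRUE),
    stringsAsFactors = FALSE)
  df
}

.parse_months <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

#' Per-year covariate matrix from monthly series and a roster
#'
#' @param climate a `climate_series` data frame covering all indices.
#' @param roster a roster data frame (see [climate_roster()]).
#' @param years integer vector of target years (rows of the result).
#' @return Numeric matrix `years x variables` of raw (unstandardised)
#'   seasonal means; `rownames` are years.
#' @export
build_covariates <- function(climate, roster = climate_roster(), years) {
  years <- as.integer(years)
  X <- matrix(NA_real_, nrow = length(years), ncol = nrow(roster),
              dimnames = list(years, roster$name))
  for (j in seq_len(nrow(roster))) {
    sub <- climate[climate$index == roster$index[j], , drop = FALSE]
    mo <- .parse_months(roster$months[j])
    for (i in seq_along(years)) {
      X[i, j] <- seasonal_mean(sub, mo, roster$lag_years[j], years[i],
                               index = roster$index[j])
    }
  }
  X
}

#' Standardise to mean 0, standard deviation 1
#'
#' @param values numeric vector (optionally named by year).
#' @return z-scores; error on zero variance or fewer than 2 values.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  s <- stats::sd(values)
  if (!is.finite(s) || s < 1e-12) stop("zero variance: cannot standardize")
  (values - mean(values)) / s
}

#' @rdname standardize
#' @param X numeric matrix; columns standardised independently.
#' @export
standardize_matrix <- function(X) {
  out <- apply(X, 2, standardize)
  dimnames(out) <- dimnames(X)
  out
}

#' Drop the weaker member of highly correlated covariate pairs
#'
#' Greedy screen: while any retained pair has `|Pearson r| >=
#' r_threshold`, drop the involved variable with the lowest top-model
#' contribution (ties: the variable occurring later in `order` is
#' dropped, keeping the earlier-listed one).  Deterministic given inputs.
#'
#' @param X numeric matrix of covariates (columns named).
#' @param contributions named numeric, a contribution score per column.
#' @param r_threshold absolute-correlation threshold (default 0.7).
#' @param priority character vector giving priority order for tie-breaks
#'   (default: column order of `X`).
#' @return Character vector of retained column names, in `priority` order.
#' @export
collinearity_screen <- function(X, contributions, r_threshold = 0.7,
                                priority = colnames(X)) {
  retained <- colnames(X)
  if (any(!retained %in% names(contributions))) {
    stop("contributions missing for: ",
         paste(setdiff(retained, names(contributions)), collapse = ", "))
  }
  repeat {
    if (length(retained) < 2) break
    C <- abs(stats::cor(X[, retained, drop = FALSE]))
    diag(C) <- 0
    if (max(C) < r_threshold) break
    involved <- retained[unique(as.vector(which(C >= r_threshold,
                                                arr.ind = TRUE)))]
    sc <- contributions[involved]
    # lowest contribution first; among equals drop the later-listed
    ord <- order(sc, -match(involved, priority))
    retained <- setdiff(retained, involved[ord[1]])
  }
  retained[order(match(retained, priority))]
}
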