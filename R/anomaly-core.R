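#' Cumulative percentage arrival curve for one season
#'
#' Daily counts are transformed to daily percentages of the season total and
#' summed, giving a non-decreasing curve that ends at exactly 100.  Using
#' percentages (rather than raw counts) gives each year equal weight in the
#' multiyear baseline regardless of how many birds were caught.
#'
#' @param season a `season_counts` object, or a numeric vector of daily
#'   counts.
#' @return A numeric vector of class `cum_curve` (one value per window day,
#'   in `[0, 100]`), with attribute `owner` = the season's year when known.
#' @export
cumulative_percent <- function(season) {
  counts <- if (inherits(season, "season_counts")) season$counts else season
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("season total must be positive; filter seasons first")
  values <- 100 * cumsum(as.numeric(counts)) / total
  structure(values,
            owner = if (inherits(season, "season_counts")) season$year else NA_integer_,
            class = "cum_curve")
}

.curve_values <- function(x) as.numeric(unclass(x))

#' Multiyear baseline arrival curve
#'
#' Unweighted elementwise mean of per-year cumulative curves, so every year
#' contributes equally.  Monotone by construction.
#'
#' @param curves list of `cum_curve` objects (or numeric vectors) of equal
#'   length; at least two.
#' @return A `cum_curve` with `owner = "baseline"`.
#' @export
multiyear_baseline <- function(curves) {
  if (length(curves) < 2) stop("need at least 2 year curves for a baseline")
  lens <- vapply(curves, length, integer(1))
  if (length(unique(lens)) != 1) stop("curves have mismatched lengths")
  m <- do.call(rbind, lapply(curves, .curve_values))
  structure(colMeans(m), owner = "baseline", class = "cum_curve")
}

#' Annual Anomaly (days) of a year's passage against the baseline
#'
#' The anomaly over days `day_lo..day_hi` is
#' \deqn{AA = \sum_d (\bar C(d) - C_y(d)) / 100}
#' where \eqn{\bar C} is the baseline and \eqn{C_y} the year's cumulative
#' percentage curve.  Positive values mean the year's passage ran later
#' than the baseline within that range; the full-window call gives the
#' overall Annual Anomaly.  Units are days because each summand is a
#' (dimensionless) proportion shortfall accumulated over one day.
#'
#' @param curve,baseline `cum_curve` objects (or numeric vectors) of equal
#'   length.
#' @param day_lo,day_hi inclusive day-index range (defaults: full window).
#' @return A single number, in days.
#' @export
annual_anomaly <- function(curve, baseline, day_lo = 1L,
                           day_hi = length(baseline)) {
  cv <- .curve_values(curve); bv <- .curve_values(baseline)
  if (length(cv) != length(bv)) stop("curve and baseline lengths differ")
  if (day_lo < 1 || day_hi > length(bv) || day_lo > day_hi) {
    stop("invalid day range [", day_lo, ", ", day_hi, "]")
  }
  r <- day_lo:day_hi
  sum(bv[r] - cv[r]) / 100
}

#' First day the baseline curve reaches a percentile
#'
#' First-crossing rule: the smallest day index `d` with
#' `baseline[d] >= q` (tolerance 1e-9 absorbs floating error at 100).
#'
#' @param baseline a `cum_curve` (or numeric vector).
#' @param q percentile in `(0, 100]`.
#' @return Integer day index.
#' @export
percentile_date <- function(baseline, q) {
  if (q <= 0 || q > 100) stop("percentile must be in (0, 100]")
  bv <- .curve_values(baseline)
  d <- which(bv >= q - 1e-9)
  if (!length(d)) stop("baseline never reaches ", q, "%")
  d[1]
}

.main_ranges <- data.frame(
  label = c("MP1", "MP2", "MP3"),
  pct_lo = c(0L, 34L, 67L), pct_hi = c(33L, 66L, 100L),
  stringsAsFactors = FALSE)

.sub_ranges <- data.frame(
  label = paste0("SP", 1:9),
  pct_lo = c(0L, 11L, 21L, 31L, 41L, 51L, 61L, 71L, 81L),
  pct_hi = c(20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L),
  stringsAsFactors = FALSE)

#' Default percentile grids
#'
#' `main_period_ranges()` gives the three non-overlapping thirds of passage
#' (0–33, 34–66, 67–100 percent); `sub_period_ranges()` the nine
#' overlapping 20-percentile windows stepped by 10 (0–20, 11–30, ...,
#' 81–100, integer bounds as conventionally printed).
#'
#' @return data frame with columns `label`, `pct_lo`, `pct_hi`.
#' @export
main_period_ranges <- function() .main_ranges

#' @rdname main_period_ranges
#' @export
sub_period_ranges <- function() .sub_ranges

#' Bind percentile ranges to concrete day ranges on the baseline
#'
#' Each range's upper day is the baseline's first crossing of `pct_hi`.
#' The lower day is the window start when `pct_lo = 0`; otherwise it is the
#' first crossing of `pct_lo` (overlapping sub-periods), or, when
#' `contiguous = TRUE`, one day after the previous range's upper day so
#' that the main periods partition the window exactly.
#'
#' @param baseline a `cum_curve`.
#' @param ranges data frame with `label`, `pct_lo`, `pct_hi` (see
#'   [main_period_ranges()]).
#' @param contiguous logical; `TRUE` for the non-overlapping main periods.
#' @return A `period_spec` data frame with added `day_lo`, `day_hi`.
#' @export
build_periods <- function(baseline, ranges, contiguous = FALSE) {
  stopifnot(all(c("label", "pct_lo", "pct_hi") %in% names(ranges)))
  if (any(ranges$pct_lo >= ranges$pct_hi)) stop("pct_lo must be < pct_hi")
  n <- nrow(ranges)
  day_lo <- day_hi <- integer(n)
  for (i in seq_len(n)) {
    # a 100th-percentile bound always extends to the window end (the curve
    # may flatten at 100 early; the closing period still owns those days,
    # which is what guarantees that contiguous periods partition the window)
    day_hi[i] <- if (ranges$pct_hi[i] >= 100) length(.curve_values(baseline))
      else percentile_date(baseline, ranges$pct_hi[i])
    day_lo[i] <- if (ranges$pct_lo[i] == 0) {
      1L
    } else if (contiguous) {
      percentile_date(baseline, ranges$pct_hi[i - 1]) + 1L
    } else {
      percentile_date(baseline, ranges$pct_lo[i])
    }
    if (day_lo[i] > day_hi[i]) {
      stop("period '", ranges$label[i], "' produces an empty day span")
    }
  }
  out <- data.frame(label = ranges$label, pct_lo = ranges$pct_lo,
                    pct_hi = ranges$pct_hi, day_lo = day_lo, day_hi = day_hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("period_spec", "data.frame")
  out
}

#' Decompose a year's anomaly over a set of periods
#'
#' One [annual_anomaly()] per period.  For contiguous main periods built
#' with [build_periods()] the per-period anomalies sum exactly to the
#' full-window anomaly.
#'
#' @inheritParams annual_anomaly
#' @param periods a `period_spec` data frame.
#' @param year optional year label for the output.
#' @return data frame: `year`, `period`, `pct_lo`, `pct_hi`, `day_lo`,
#'   `day_hi`, `aa_days`.
#' @export
decompose_anomaly <- function(curve, baseline, periods, year = NA_integer_) {
  aa <- vapply(seq_len(nrow(periods)), function(i) {
    annual_anomaly(curve, baseline, periods$day_lo[i], periods$day_hi[i])
  }, numeric(1))
  if (is.na(year) && !is.null(attr(curve, "owner"))) year <- attr(curve, "owner")
  data.frame(year = as.integer(year), period = periods$label,
             pct_lo = periods$pct_lo, pct_hi = periods$pct_hi,
             day_lo = periods$day_lo, day_hi = periods$day_hi,
             aa_days = aa, stringsAsFactors = FALSE)
}

#' Anomaly table for all years and periods
#'
#' @param curves named (by year) list of `cum_curve` objects.
#' @param baseline the multiyear baseline.
#' @param periods a `period_spec`.
#' @param sign_flip if `TRUE`, negate all anomalies (late = negative);
#'   the default convention is positive = later than baseline.
#' @return Long data frame, one row per (year, period).
#' @export
anomaly_table <- function(curves, baseline, periods, sign_flip = FALSE) {
  yrs <- if (is.null(names(curves))) rep(NA_integer_, length(curves)) else
    suppressWarnings(as.integer(names(curves)))
  out <- do.call(rbind, lapply(seq_along(curves), function(i) {
    decompose_anomaly(curves[[i]], baseline, periods, year = yrs[i])
  }))
  if (sign_flip) out$aa_days <- -out$aa_days
  rownames(out) <- NULL
  out
}
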