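#' Season windows for spring and autumn passage
#'
#' A season window is a fixed calendar range, identical across years, over
#' which daily capture counts are tallied.  The spring window is 1 April to
#' 15 May (45 days); the autumn window is 14 August to 29 October (77 days).
#' Day indices are positions within the window (day 1 = first day), so leap
#' years do not affect either window.
#'
#' @param label `"spring"` or `"autumn"`.
#' @return An object of class `season_window`: a list with elements `label`,
#'   `start` and `end` (integer `c(month, day)` pairs) and `n_days`.
#' @examples
#' season_window("spring")$n_days  # 45
#' @export
season_window <- function(label = c("spring", "autumn")) {
  label <- match.arg(label)
  sw <- if (label == "spring") {
    list(label = "spring", start = c(4L, 1L), end = c(5L, 15L))
  } else {
    list(label = "autumn", start = c(8L, 14L), end = c(10L, 29L))
  }
  # n_days computed in an arbitrary non-leap year; both windows avoid February
  sw$n_days <- as.integer(.window_end(sw, 2001L) - .window_start(sw, 2001L)) + 1L
  class(sw) <- "season_window"
  sw
}

.window_start <- function(window, year) {
  as.Date(sprintf("%04d-%02d-%02d", year, window$start[1], window$start[2]))
}

.window_end <- function(window, year) {
  as.Date(sprintf("%04d-%02d-%02d", year, window$end[1], window$end[2]))
}

#' Calendar dates of a season window in a given year
#'
#' @param window a [season_window()].
#' @param year integer calendar year.
#' @return A `Date` vector of length `window$n_days`.
#' @export
window_dates <- function(window, year) {
  seq(.window_start(window, year), .window_end(window, year), by = "day")
}

#' Map capture dates to day indices within a season window
#'
#' @inheritParams window_dates
#' @param dates a `Date` vector.
#' @return Integer day indices (1-based); `NA` for dates outside the window.
#' @export
day_index <- function(dates, window, year) {
  idx <- as.integer(dates - .window_start(window, year)) + 1L
  idx[idx < 1L | idx > window$n_days] <- NA_integer_
  idx
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("<season_window> %s: %02d-%02d to %02d-%02d (%d days)\n",
              x$label, x$start[1], x$start[2], x$end[1], x$end[2], x$n_days))
  invisible(x)
}
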