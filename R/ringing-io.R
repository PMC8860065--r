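#' Read a capture table
#'
#' Reads one-capture-per-row delimited text.  Required logical columns are
#' `ring_id`, `date` (ISO 8601), `age_class` and `site`; `schema` maps them
#' to the file's actual column names.  Dates failing to parse abort the run
#' with the offending row numbers, so silent data loss is impossible.
#'
#' Age classes are normalised to lower case with underscores; anything
#' outside `full_grown`, `juvenile`, `adult`, `unknown` becomes `"unknown"`
#' with a warning (spring birds are conventionally aged "full grown",
#' autumn birds "juvenile"/"adult").
#'
#' @param path path to a CSV file.
#' @param schema named character vector or list mapping the logical names
#'   `ring_id`, `date`, `age_class`, `site` to column names in the file.
#' @return A data frame of class `capture_records` with columns `ring_id`
#'   (character), `date` (`Date`), `age_class`, `site`.
#' @export
load_captures <- function(path,
                          schema = c(ring_id = "ring_id", date = "date",
                                     age_class = "age_class", site = "site")) {
  if (!file.exists(path)) stop("capture file not found: ", path)
  schema <- unlist(schema)
  required <- c("ring_id", "date", "age_class", "site")
  if (!all(required %in% names(schema))) {
    stop("schema must map: ", paste(setdiff(required, names(schema)), collapse = ", "))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  missing_cols <- setdiff(unname(schema[required]), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    ring_id   = raw[[schema[["ring_id"]]]],
    date_raw  = raw[[schema[["date"]]]],
    age_class = raw[[schema[["age_class"]]]],
    site      = raw[[schema[["site"]]]],
    stringsAsFactors = FALSE
  )
  dates <- as.Date(out$date_raw, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | is.na(out$date_raw) | out$date_raw == "")
  if (length(bad)) {
    stop("unparseable date(s) in ", path, " at row(s): ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) sprintf(" (and %d more)", length(bad) - 20) else "")
  }
  age <- tolower(gsub("[ -]", "_", trimws(out$age_class)))
  known <- c("full_grown", "juvenile", "adult", "unknown")
  if (any(!age %in% known)) {
    warning("unrecognised age_class value(s) coerced to 'unknown': ",
            paste(unique(out$age_class[!age %in% known]), collapse = ", "))
    age[!age %in% known] <- "unknown"
  }
  res <- data.frame(ring_id = out$ring_id, date = dates, age_class = age,
                    site = out$site, stringsAsFactors = FALSE)
  class(res) <- c("capture_records", "data.frame")
  res
}

#' Deduplicate to first capture per season
#'
#' Keeps, for each ring id, only the chronologically first capture falling
#' inside the given (year, window); all other records are dropped.  Ties on
#' the same day collapse to one record.  The operation is idempotent and
#' order-independent.
#'
#' @param records a `capture_records` data frame (see [load_captures()]).
#' @param window a [season_window()].
#' @param year integer calendar year of the season.
#' @return A `capture_records` data frame with at most one row per ring id.
#' @export
first_captures <- function(records, window, year) {
  lo <- .window_start(window, year)
  hi <- .window_end(window, year)
  keep <- records$date >= lo & records$date <= hi
  rec <- records[keep, , drop = FALSE]
  rec <- rec[order(rec$date, rec$ring_id), , drop = FALSE]
  rec <- rec[!duplicated(rec$ring_id), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("capture_records", "data.frame")
  rec
}

#' Daily capture counts over a season window
#'
#' Tallies deduplicated records into one count per calendar day of the
#' window.  Days without ringing inside the window are zero-capture days
#' (the sampling protocol is daily and continuous; no effort imputation).
#'
#' @param records records already deduplicated with [first_captures()].
#' @inheritParams first_captures
#' @return An object of class `season_counts`: list with `year`, `window`,
#'   `counts` (integer vector of length `window$n_days`), `dates`, `total`.
#' @export
daily_counts <- function(records, window, year) {
  idx <- day_index(records$date, window, year)
  idx <- idx[!is.na(idx)]
  counts <- tabulate(idx, nbins = window$n_days)
  structure(list(year = as.integer(year), window = window,
                 counts = as.integer(counts),
                 dates = window_dates(window, year),
                 total = as.integer(sum(counts))),
            class = "season_counts")
}

#' @export
print.season_counts <- function(x, ...) {
  cat(sprintf("<season_counts> %s %d: %d birds over %d days\n",
              x$window$label, x$year, x$total, x$window$n_days))
  invisible(x)
}

#' Filter seasons by a minimum season total
#'
#' Seasons with fewer captures than `min_total` are excluded from all
#' downstream analyses (anomaly baseline included).  Inclusion is
#' `total >= min_total`.
#'
#' @param all_counts list of `season_counts`.
#' @param min_total inclusion threshold (default 30 birds).
#' @return list with `included` (list of `season_counts`) and
#'   `excluded_years` (sorted integer vector).
#' @export
filter_seasons <- function(all_counts, min_total = 30L) {
  stopifnot(min_total >= 0)
  totals <- vapply(all_counts, function(s) s$total, integer(1))
  keep <- totals >= min_total
  list(included = all_counts[keep],
       excluded_years = sort(vapply(all_counts[!keep], function(s) s$year,
                                    integer(1))))
}

#' Juveniles caught per 50 mist nets
#'
#' Effort-normalised autumn productivity index: the season's juvenile total
#' divided by the number of nets operated that season, times 50.
#'
#' @param juvenile_total non-negative integer(s).
#' @param nets positive integer(s), nets operated that season.
#' @return numeric, juveniles per 50 nets.
#' @export
juveniles_per_50_nets <- function(juvenile_total, nets) {
  if (any(nets <= 0)) stop("nets must be positive")
  if (any(juvenile_total < 0)) stop("juvenile_total must be non-negative")
  juvenile_total / nets * 50
}

#' Build the autumn effort index table
#'
#' Counts juveniles (first capture per season, age class `"juvenile"`)
#' within the autumn window for each year of an effort table and normalises
#' per 50 nets.
#'
#' @param records a `capture_records` data frame (all seasons pooled).
#' @param effort data frame with columns `year`, `season`, `nets`; only
#'   `season == "autumn"` rows are used.
#' @return data frame with columns `year`, `juveniles`, `nets`, `per50`.
#' @export
effort_index <- function(records, effort) {
  aut <- effort[effort$season == "autumn", , drop = FALSE]
  win <- season_window("autumn")
  rows <- lapply(seq_len(nrow(aut)), function(i) {
    y <- aut$year[i]
    fc <- first_captures(records, win, y)
    nj <- sum(fc$age_class == "juvenile")
    data.frame(year = as.integer(y), juveniles = nj, nets = aut$nets[i],
               per50 = juveniles_per_50_nets(nj, aut$nets[i]))
  })
  do.call(rbind, rows)
}
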