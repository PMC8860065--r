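# Fixture builders shared across test files.  Everything is generated in
# code; no data files are read from disk except temp files written here.

make_records <- function(ring_id, date, age_class = "full_grown",
                         site = "TEST") {
  df <- data.frame(ring_id = ring_id, date = as.Date(date),
                   age_class = rep_len(age_class, length(ring_id)),
                   site = rep_len(site, length(ring_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("capture_records", "data.frame")
  df
}

write_capture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a random plausible year curve over n window days (unimodal-ish counts)
random_curve <- function(n = 45, total = NULL) {
  if (is.null(total)) total <- sample(30:400, 1)
  mu <- runif(1, 10, n - 10)
  sd <- runif(1, 3, 10)
  dens <- diff(pnorm(0:n, mu, sd))
  dens <- dens / sum(dens)
  cumulative_percent(as.integer(rmultinom(1, total, dens)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small standardized design matrix with named columns
random_design <- function(n, p, prefix = "x") {
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0(prefix, seq_len(p))))
  X
}
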