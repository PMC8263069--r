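#' Uniformly sampled time series
#'
#' Light container for a single-channel, uniformly sampled signal.
#'
#' @param values numeric vector of samples (finite, length >= 2).
#' @param dt sampling interval in seconds (> 0).
#' @return An object of class `bd_timeseries`: the numeric vector with a
#'   `dt` attribute.
#' @export
bd_timeseries <- function(values, dt) {
  values <- as.numeric(values)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (length(values) < 2L) stop("time series must have length >= 2")
  if (!all(is.finite(values))) stop("time series values must all be finite")
  structure(values, dt = dt, class = "bd_timeseries")
}

#' Non-negative amplitude envelope
#'
#' @param values non-negative numeric vector (amplitude units).
#' @param dt sampling interval in seconds.
#' @return An object of class `bd_envelope`.
#' @export
bd_envelope <- function(values, dt) {
  values <- as.numeric(values)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (!all(is.finite(values))) stop("envelope values must all be finite")
  if (any(values < 0)) stop("envelope values must be non-negative")
  structure(values, dt = dt, class = "bd_envelope")
}

ts_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) stop("object carries no `dt` attribute; wrap it with ",
                        "bd_timeseries() or bd_envelope()")
  dt
}

#' @export
print.bd_timeseries <- function(x, ...) {
  cat(sprintf("<bd_timeseries> %d samples @ %g Hz (%.4g s)\n",
              length(x), 1 / ts_dt(x), length(x) * ts_dt(x)))
  invisible(x)
}

#' @export
print.bd_envelope <- function(x, ...) {
  cat(sprintf("<bd_envelope> %d samples @ %g Hz, range [%.4g, %.4g]\n",
              length(x), 1 / ts_dt(x), min(x), max(x)))
  invisible(x)
}

#' Read a time series from a one-column text/CSV file
#'
#' The file holds one sample per row in a single `value` column (header
#' optional). A comment line `# fs_hz=<float>` supplies the sampling rate;
#' `fs` overrides it.
#'
#' @param path file path.
#' @param fs sampling rate override in Hz (optional).
#' @return A [bd_timeseries()].
#' @export
read_timeseries <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) && grepl("^[A-Za-z]", body[1])) body <- body[-1]
  body <- body[nzchar(trimws(body))]
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value at data row %d of %s", bad, path))
  }
  if (is.null(fs)) {
    m <- regmatches(hdr, regexpr("fs_hz=\\s*[0-9.eE+-]+", hdr))
    m <- unlist(m)
    if (!length(m)) stop("sampling rate required: no `# fs_hz=` header and ",
                         "no `fs` argument")
    fs <- as.numeric(sub("fs_hz=\\s*", "", m[1]))
  }
  bd_timeseries(vals, dt = 1 / fs)
}

#' Write a time series to a one-column CSV with an `# fs_hz=` header
#'
#' @param ts a [bd_timeseries()] or [bd_envelope()].
#' @param path destination path.
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.12g", 1 / ts_dt(ts)), con)
  writeLines("value", con)
  writeLines(sprintf("%.17g", as.numeric(ts)), con)
  invisible(path)
}

#' Write a threshold profile to CSV
#'
#' Columns: `percentile, threshold, mean_duration_s, sem_duration_s,
#' mean_amplitude, sem_amplitude, rate_hz, n_bursts`.
#'
#' @param profile a `bd_profile` data frame from [burst_profiles()].
#' @param path destination path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a threshold profile CSV written by [write_profile()]
#' @param path file path.
#' @return A `bd_profile` data frame.
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("bd_profile", "data.frame")
  df
}
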