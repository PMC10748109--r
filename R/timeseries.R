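#' Construct a single-channel series
#'
#' A `channel_series` holds one hard-sensor channel of a batch run on a
#' strictly increasing, uniformly spaced time grid. Inactive samples (sensor
#' offline, e.g. during a shutdown) are carried as `NA`; the per-sample
#' activity flag is `!is.na(values)`.
#'
#' @param channel One of [CHANNELS].
#' @param time_days Elapsed time from run start, in days; strictly increasing
#'   and uniformly spaced (relative tolerance `1e-6` of the step).
#' @param values Numeric readings in the channel's units; `NA` marks inactive
#'   samples.
#' @return An object of class `channel_series` with fields `channel`,
#'   `time_days`, `values`, `interval_s` (the inferred sampling interval in
#'   seconds) and `active` (logical per sample).
#' @export
channel_series <- function(channel, time_days, values) {
  channel <- match.arg(channel, CHANNELS)
  if (!is.numeric(time_days) || length(time_days) < 2L)
    stopf("`time_days` must be numeric with >= 2 samples")
  if (length(values) != length(time_days))
    stopf("`values` and `time_days` lengths differ (%d vs %d)",
          length(values), length(time_days))
  dt <- diff(time_days)
  if (any(dt <= 0)) stopf("timestamps must be strictly increasing")
  step <- stats::median(dt)
  if (any(abs(dt - step) > 1e-6 * step))
    stopf("non-uniform time grid for channel %s (max deviation %.3g of step)",
          channel, max(abs(dt - step)) / step)
  values <- as.numeric(values)
  if (any(is.infinite(values)))
    stopf("active values must be finite; use NA for inactive samples")
  structure(
    list(channel = channel, time_days = as.numeric(time_days),
         values = values, interval_s = step * 86400,
         active = !is.na(values)),
    class = "channel_series")
}

#' @export
length.channel_series <- function(x) length(x$values)

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s: %d samples @ %.3g s, %.1f%% active\n",
              x$channel, length(x), x$interval_s, 100 * mean(x$active)))
  invisible(x)
}

#' Construct a batch run
#'
#' A `batch_run` is one complete cell-expansion cycle: the eight channels of
#' [CHANNELS] on a common uniform time grid.
#'
#' @param run_id Character label for the run.
#' @param time_days Common time grid, days from run start.
#' @param channels Named list (names = [CHANNELS]) of numeric value vectors,
#'   `NA` marking inactive samples. Missing channels are filled with all-`NA`
#'   (inactive) series.
#' @param metadata Optional named list of free-form provenance.
#' @return An object of class `batch_run` with fields `run_id`, `time_days`,
#'   `interval_s`, `channels` (named list of value vectors) and `metadata`.
#' @export
batch_run <- function(run_id, time_days, channels, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)))
    stopf("`channels` must be a named list")
  unknown <- setdiff(names(channels), CHANNELS)
  if (length(unknown))
    stopf("unknown channel(s): %s", paste(unknown, collapse = ", "))
  n <- length(time_days)
  full <- stats::setNames(vector("list", length(CHANNELS)), CHANNELS)
  for (ch in CHANNELS) {
    v <- channels[[ch]] %||% rep(NA_real_, n)
    if (length(v) != n)
      stopf("channel %s has %d values; grid has %d", ch, length(v), n)
    full[[ch]] <- as.numeric(v)
  }
  # validate the grid once via an arbitrary channel constructor
  probe <- channel_series("T", time_days, full[["T"]])
  structure(
    list(run_id = as.character(run_id), time_days = as.numeric(time_days),
         interval_s = probe$interval_s, channels = full,
         metadata = metadata),
    class = "batch_run")
}

#' @export
print.batch_run <- function(x, ...) {
  act <- vapply(x$channels, function(v) mean(!is.na(v)), numeric(1))
  cat(sprintf("<batch_run> %s: %d samples @ %.3g s (%.2f days)\n",
              x$run_id, length(x$time_days), x$interval_s,
              max(x$time_days)))
  cat("  active: ",
      paste(sprintf("%s %.0f%%", names(act), 100 * act), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract one channel of a batch run
#'
#' @param run A [batch_run()].
#' @param channel One of [CHANNELS].
#' @return A [channel_series()].
#' @export
run_channel <- function(run, channel) {
  channel <- match.arg(channel, CHANNELS)
  channel_series(channel, run$time_days, run$channels[[channel]])
}

#' Is a channel active (has any readings)?
#' @param run A [batch_run()].
#' @param channel One of [CHANNELS].
#' @return `TRUE` if the channel has at least one non-missing sample.
#' @export
channel_active <- function(run, channel) {
  any(!is.na(run$channels[[match.arg(channel, CHANNELS)]]))
}

#' Trailing rolling mean and standard deviation
#'
#' Computes the trailing-window mean and standard deviation of a channel at
#' every timestamp with a full window; the warm-up prefix (first
#' `n_window - 1` samples) is `NA`. The window is the previous
#' `window_min` minutes *including* the current sample; callers that need the
#' window to exclude the current sample (the disturbance indicator does)
#' shift the result by one sample.
#'
#' The standard deviation uses the population estimator (divide by n) by
#' default; the sample form (n-1) is available via `estimator`.
#'
#' @param series A [channel_series()].
#' @param window_min Window duration in minutes; must span at least 2 samples.
#' @param estimator `"population"` (default) or `"sample"`.
#' @return An object of class `window_stats`: a data.frame with columns
#'   `time_days`, `mean`, `sd`, and attributes `window_samples`,
#'   `window_min`, `estimator`.
#' @export
rolling_stats <- function(series, window_min,
                          estimator = c("population", "sample")) {
  stopifnot(inherits(series, "channel_series"))
  estimator <- match.arg(estimator)
  n <- window_samples(window_min, series$interval_s)
  x <- series$values
  # centring improves conditioning of the E[x^2] - E[x]^2 form
  c0 <- mean(x, na.rm = TRUE)
  if (!is.finite(c0)) c0 <- 0
  xc <- x - c0
  m1 <- data.table::frollmean(xc, n, algo = "exact")
  m2 <- data.table::frollmean(xc^2, n, algo = "exact")
  v <- pmax(m2 - m1^2, 0)
  if (estimator == "sample") v <- v * n / (n - 1)
  out <- data.frame(time_days = series$time_days, mean = m1 + c0,
                    sd = sqrt(v))
  structure(out, class = c("window_stats", "data.frame"),
            window_samples = n, window_min = window_min,
            estimator = estimator)
}

#' Resample batch runs onto a coarser uniform grid
#'
#' Aggregates each run by trailing means over consecutive blocks of the source
#' grid: the target interval must be an integer multiple of the source
#' interval. Output sample `j` is the mean of source samples
#' `((j-1)*m + 1):(j*m)` (`m` the interval ratio) and is stamped with the time
#' of the block's last source sample. Activity is propagated: a target sample
#' is active if at least one source sample in its block is active (mean over
#' the active ones), and `NA` otherwise.
#'
#' @param runs A list of [batch_run()] objects (a single run is accepted).
#' @param interval_s Target sampling interval in seconds.
#' @return A list of resampled [batch_run()] objects (same length as input).
#' @export
align_runs <- function(runs, interval_s) {
  if (inherits(runs, "batch_run")) runs <- list(runs)
  assert_scalar_number(interval_s, "interval_s", positive = TRUE)
  lapply(runs, function(run) {
    ratio <- interval_s / run$interval_s
    m <- as.integer(round(ratio))
    if (abs(ratio - m) > 1e-6 || m < 1L)
      stopf("target interval %g s is not an integer multiple of source %g s",
            interval_s, run$interval_s)
    if (m == 1L) return(run)
    n_out <- length(run$time_days) %/% m
    if (n_out < 2L)
      stopf("run %s too short for %g s grid", run$run_id, interval_s)
    idx_last <- seq_len(n_out) * m
    grp <- rep(seq_len(n_out), each = m)
    agg <- lapply(run$channels, function(v) {
      v <- v[seq_len(n_out * m)]
      s <- tapply(v, grp, function(b) {
        b <- b[!is.na(b)]
        if (length(b)) mean(b) else NA_real_
      })
      as.numeric(s)
    })
    batch_run(run$run_id, run$time_days[idx_last], agg,
              metadata = c(run$metadata,
                           list(resampled_from_s = run$interval_s)))
  })
}

#' Read a batch run from CSV
#'
#' Expected header: `time_days,T,DO,pH,GasFL,Glu,Lac,O2,CO2`; one row per
#' sample, empty cells marking inactive samples, `.` decimal separator.
#'
#' @param path CSV file path.
#' @param run_id Run label; defaults to the file name without extension.
#' @return A [batch_run()].
#' @export
read_batch_csv <- function(path, run_id = NULL) {
  if (!file.exists(path)) stopf("batch CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric", na.strings = "")
  need <- c("time_days", CHANNELS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("batch CSV %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  batch_run(run_id %||% sub("\\.[^.]*$", "", basename(path)),
            df$time_days, as.list(df[CHANNELS]),
            metadata = list(source = path))
}

#' Write a batch run to CSV
#'
#' Inverse of [read_batch_csv()]; inactive samples become empty cells.
#'
#' @param run A [batch_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(run, path) {
  cols <- c(list(time_days = run$time_days), run$channels)
  txt <- vapply(cols, function(v)
    ifelse(is.na(v), "", formatC(v, digits = 17, format = "g")),
    character(length(run$time_days)))
  txt <- rbind(names(cols), txt)
  writeLines(apply(txt, 1L, paste, collapse = ","), path)
  invisible(path)
}
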