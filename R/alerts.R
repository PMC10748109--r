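#' Construct an alert series
#'
#' Common container for every smart sensor's output: the continuous score and
#' the thresholded binary alert on the batch time grid. Warm-up or otherwise
#' undefined scores are `NA` with alert 0 (no evidence, no alert).
#'
#' @param time_days Time grid, days.
#' @param score Continuous sensor output (units depend on the sensor).
#' @param alert Binary 0/1 vector.
#' @param sensor Sensor label, ideally one of [SENSORS].
#' @return Data frame of class `alert_series` with columns `time_days`,
#'   `score`, `alert` and attribute `sensor`.
#' @export
alert_series <- function(time_days, score, alert, sensor = "sensor") {
  alert <- as.integer(alert)
  if (any(is.na(alert))) stopf("alert values must be 0/1, not NA")
  if (!all(alert %in% 0:1)) stopf("alert values must be 0/1")
  if (length(score) != length(time_days) ||
      length(alert) != length(time_days))
    stopf("alert_series columns must share the grid length")
  structure(data.frame(time_days = time_days, score = as.numeric(score),
                       alert = alert),
            class = c("alert_series", "data.frame"), sensor = sensor)
}

#' @export
print.alert_series <- function(x, ...) {
  cat(sprintf("<alert_series> %s: %d samples, %d alert(s)\n",
              attr(x, "sensor"), nrow(x), sum(x$alert)))
  invisible(x)
}

#' Write an alert series to CSV (`time_days,score,alert`)
#' @param x An [alert_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alert_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
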