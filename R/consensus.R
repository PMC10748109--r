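#' Assemble an alert matrix from alert streams
#'
#' Binds smart-sensor alert streams (0/1 columns) on a common time grid.
#'
#' @param alerts Named list of [alert_series()] (names default to each
#'   series' `sensor` attribute).
#' @return Data frame of class `alert_matrix`: `time_days` plus one binary
#'   column per sensor.
#' @export
alert_matrix <- function(alerts) {
  if (!length(alerts)) stopf("no alert streams supplied")
  if (is.null(names(alerts)) || any(names(alerts) == ""))
    names(alerts) <- vapply(alerts, attr, "", "sensor")
  t0 <- alerts[[1]]$time_days
  for (a in alerts)
    if (length(a$time_days) != length(t0) ||
        max(abs(a$time_days - t0)) > 1e-9)
      stopf("alert streams must share the time grid")
  out <- data.frame(time_days = t0)
  for (nm in names(alerts)) out[[nm]] <- alerts[[nm]]$alert
  validate_alert_matrix(out)
}

validate_alert_matrix <- function(mat) {
  sensor_cols <- setdiff(names(mat), "time_days")
  for (nm in sensor_cols) {
    v <- mat[[nm]]
    if (any(is.na(v)) || !all(v %in% 0:1))
      stopf("alert matrix column %s is not binary 0/1", nm)
    mat[[nm]] <- as.integer(v)
  }
  structure(mat, class = c("alert_matrix", "data.frame"),
            sensors = sensor_cols)
}

#' Read/write an alert matrix CSV (`time_days` + one 0/1 column per sensor)
#' @param path CSV path.
#' @return An `alert_matrix`.
#' @export
read_alert_matrix_csv <- function(path) {
  if (!file.exists(path)) stopf("alert matrix CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_days" %in% names(df)) stopf("missing `time_days` column")
  validate_alert_matrix(df)
}

#' @rdname read_alert_matrix_csv
#' @param mat An `alert_matrix`.
#' @export
write_alert_matrix_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simultaneous-alert count per timestamp
#'
#' @param mat An `alert_matrix` from [alert_matrix()].
#' @return Integer vector: per-timestamp number of alerting sensors.
#' @export
count_simultaneous <- function(mat) {
  mat <- validate_alert_matrix(mat)
  cols <- attr(mat, "sensors")
  as.integer(rowSums(as.matrix(as.data.frame(mat)[cols])))
}

#' Detect consensus events from simultaneous-alert counts
#'
#' A consensus event is a maximal run of timestamps where at least
#' `min_sensors` smart sensors alert simultaneously; above-threshold runs
#' separated by a gap shorter than `merge_gap_min` are merged into one event.
#' Events shorter than `min_duration_min` can optionally be dropped
#' (default 0: keep all, including single-sample events).
#'
#' @param counts Integer count series, e.g. from [count_simultaneous()].
#' @param time_days Matching time grid, days.
#' @param min_sensors Consensus threshold (default 3, of the 6 sensors).
#' @param merge_gap_min Gap below which adjacent events merge, minutes
#'   (default 30).
#' @param min_duration_min Optional minimum event duration, minutes
#'   (default 0 = off).
#' @return Data frame of class `consensus_events`: `start_days`, `end_days`,
#'   `peak_count` (max simultaneous count inside the event).
#' @export
detect_events <- function(counts, time_days, min_sensors = 3,
                          merge_gap_min = 30, min_duration_min = 0) {
  if (length(counts) != length(time_days))
    stopf("`counts` and `time_days` lengths differ")
  if (min_sensors < 1) stopf("`min_sensors` must be >= 1")
  hit <- counts >= min_sensors
  hit[is.na(hit)] <- FALSE
  empty <- data.frame(start_days = numeric(), end_days = numeric(),
                      peak_count = integer())
  if (!any(hit))
    return(structure(empty, class = c("consensus_events", "data.frame")))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  si <- starts[r$values]
  ei <- ends[r$values]
  # merge runs separated by < merge_gap_min
  gap_days <- merge_gap_min / (24 * 60)
  merged_s <- si[1]; merged_e <- ei[1]
  if (length(si) > 1) {
    for (k in 2:length(si)) {
      if (time_days[si[k]] - time_days[merged_e[length(merged_e)]] <
          gap_days) {
        merged_e[length(merged_e)] <- ei[k]
      } else {
        merged_s <- c(merged_s, si[k])
        merged_e <- c(merged_e, ei[k])
      }
    }
  }
  peak <- mapply(function(a, b) max(counts[a:b]), merged_s, merged_e)
  out <- data.frame(start_days = time_days[merged_s],
                    end_days = time_days[merged_e],
                    peak_count = as.integer(peak))
  if (min_duration_min > 0)
    out <- out[(out$end_days - out$start_days) * 24 * 60 >=
                 min_duration_min, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("consensus_events", "data.frame"))
}

#' Per-sensor coincidence with consensus events
#'
#' For each sensor, counts the consensus events during which that sensor's
#' alert is 1 for at least one in-event timestamp.
#'
#' @param events A `consensus_events` data frame from [detect_events()].
#' @param mat The `alert_matrix` the events were derived from.
#' @return Named integer vector: detected event count per sensor.
#' @export
coincidence <- function(events, mat) {
  mat <- validate_alert_matrix(mat)
  cols <- attr(mat, "sensors")
  detected <- stats::setNames(integer(length(cols)), cols)
  t <- mat$time_days
  for (k in seq_len(nrow(events))) {
    inside <- t >= events$start_days[k] & t <= events$end_days[k]
    for (nm in cols)
      if (any(mat[[nm]][inside] == 1L)) detected[nm] <- detected[nm] + 1L
  }
  detected
}

#' Published five-run alert summary (calibration counts)
#'
#' The tabulated calibration result shipped with the package: total consensus
#' events per batch run and, per smart sensor, how many of them coincided
#' with that sensor's alerts, for five historical runs.
#'
#' @return List with `totals` (named numeric, runs 1-5) and `detected`
#'   (6 sensors x 5 runs integer matrix, rows in [SENSORS] order).
#' @export
reported_alert_summary <- function() {
  runs <- paste0("run", 1:5)
  detected <- rbind(
    SDI          = c(3, 5, 1, 5, 0),
    Boll_Glucose = c(3, 5, 6, 14, 13),
    Boll_Lactate = c(3, 4, 1, 12, 4),
    WWA_SP       = c(2, 5, 12, 7, 16),
    WWA_NSP      = c(2, 1, 14, 13, 19),
    Fuzzy        = c(2, 5, 14, 8, 21))
  colnames(detected) <- runs
  list(totals = stats::setNames(c(3, 5, 14, 14, 21), runs),
       detected = detected)
}

#' Coincidence summary statistics
#'
#' Derives the full undetected-event summary from per-run consensus-event
#' totals and per-sensor detected counts:
#' * `undetected` = total - detected, per cell;
#' * `sum_b` (per sensor) = undetected summed over runs;
#'   `pct_sum_b` = `sum_b / sum(totals)`, rounded half-up to 2 decimals;
#' * `sum_s` (per run) = undetected summed over sensors; `pct_sum_s` =
#'   `sum_s / grand` with `grand = sum(sum_s)`, rounded half-up to 2 decimals
#'   (the denominator that reproduces the published rows);
#' * per-sensor consensus percent = `100 * (1 - sum_b / sum(totals))`, per-run
#'   consensus percent = `100 * (1 - sum_s / grand)`, both rounded half-up to
#'   integers;
#' * averages of those rounded percentages (rounded half-up) — the published
#'   six-sensor average (65) is the mean of the *rounded* per-sensor figures.
#'
#' @param totals Numeric vector of total consensus events per run.
#' @param detected Sensors x runs matrix of detected counts (each cell
#'   `<=` the run total).
#' @return List of class `coincidence_table` with fields `totals`,
#'   `detected`, `undetected`, `sum_b`, `pct_sum_b`, `sum_s`, `pct_sum_s`,
#'   `grand_undetected`, `consensus_percent_sensor`, `consensus_percent_run`,
#'   `avg_consensus_sensor`, `avg_consensus_run`.
#' @export
summarize_coincidence <- function(totals, detected) {
  detected <- as.matrix(detected)
  if (ncol(detected) != length(totals))
    stopf("`detected` must have one column per run")
  tot <- matrix(totals, nrow(detected), length(totals), byrow = TRUE)
  if (any(detected < 0) || any(detected > tot))
    stopf("detected counts must lie in [0, total] for every run")
  undet <- tot - detected
  dimnames(undet) <- dimnames(detected)
  sum_b <- rowSums(undet)
  sum_s <- colSums(undet)
  grand <- sum(sum_s)
  total_events <- sum(totals)
  pct_sum_b <- round_half_up(sum_b / total_events, 2)
  pct_sum_s <- if (grand > 0) round_half_up(sum_s / grand, 2) else sum_s * 0
  cons_sensor <- round_half_up(100 * (1 - sum_b / total_events), 0)
  cons_run <- if (grand > 0)
    round_half_up(100 * (1 - sum_s / grand), 0)
  else rep(100, length(sum_s))
  names(cons_run) <- names(sum_s)
  structure(list(
    totals = totals, detected = detected, undetected = undet,
    sum_b = sum_b, pct_sum_b = pct_sum_b,
    sum_s = sum_s, pct_sum_s = pct_sum_s,
    grand_undetected = grand,
    consensus_percent_sensor = cons_sensor,
    consensus_percent_run = cons_run,
    avg_consensus_sensor = round_half_up(mean(cons_sensor), 0),
    avg_consensus_run = round_half_up(mean(cons_run), 0)),
    class = "coincidence_table")
}

#' @export
print.coincidence_table <- function(x, ...) {
  cat("<coincidence_table> undetected consensus events\n")
  tab <- cbind(x$undetected, sum_b = x$sum_b, pct_sum_b = x$pct_sum_b)
  print(tab)
  cat("sum_s:  ", paste(x$sum_s, collapse = " "),
      " (grand ", x$grand_undetected, ")\n", sep = "")
  cat("pct_sum_s:", paste(format(x$pct_sum_s), collapse = " "), "\n")
  cat(sprintf("consensus %% per sensor: %s (avg %d)\n",
              paste(x$consensus_percent_sensor, collapse = " "),
              x$avg_consensus_sensor))
  cat(sprintf("consensus %% per run:    %s (avg %d)\n",
              paste(x$consensus_percent_run, collapse = " "),
              x$avg_consensus_run))
  invisible(x)
}
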