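#' Build one sensor specification
#'
#' Per-channel configuration for the weighted-weighted-average (WWA)
#' aggregator: the setpoint (SP, controlled channels) or reference value
#' (NSP, uncontrolled channels), the static scaling weight `v`, and the
#' critical range distance that gates the sensor into the aggregate.
#'
#' @param channel One of [CHANNELS].
#' @param group `"SP"` (has a setpoint) or `"NSP"` (reference value only).
#' @param reference Either a single number or a stepwise schedule: a
#'   data.frame with columns `from_day` (first row must be 0) and `value`,
#'   for setpoints that change mid-run.
#' @param scaling_weight Static scaling weight `v` in `(0, 1]`.
#' @param critical_distance Raw channel-unit distance from the reference at or
#'   beyond which the criticality gate opens (`> 0`).
#' @return A list of class `sensor_spec`.
#' @export
sensor_spec <- function(channel, group = c("SP", "NSP"), reference,
                        scaling_weight, critical_distance) {
  channel <- match.arg(channel, CHANNELS)
  group <- match.arg(group)
  if (is.numeric(reference) && length(reference) == 1L)
    reference <- data.frame(from_day = 0, value = reference)
  if (!is.data.frame(reference) ||
      !all(c("from_day", "value") %in% names(reference)) ||
      reference$from_day[1] != 0 || is.unsorted(reference$from_day))
    stopf("`reference` must be a number or a schedule starting at day 0")
  assert_scalar_number(scaling_weight, "scaling_weight", positive = TRUE)
  if (scaling_weight > 1) stopf("`scaling_weight` must lie in (0, 1]")
  assert_scalar_number(critical_distance, "critical_distance",
                       positive = TRUE)
  structure(list(channel = channel, group = group, reference = reference,
                 scaling_weight = scaling_weight,
                 critical_distance = critical_distance),
            class = "sensor_spec")
}

#' Reference value of a sensor at given times
#' @param spec A [sensor_spec()].
#' @param time_days Numeric vector of times, days.
#' @return Numeric vector of reference values.
#' @export
reference_at <- function(spec, time_days) {
  sched <- spec$reference
  spec_idx <- findInterval(time_days, sched$from_day)
  spec_idx[spec_idx < 1L] <- 1L
  sched$value[spec_idx]
}

#' Default sensor specifications per batch run
#'
#' The tabulated calibration shipped with the platform: setpoint channels
#' Glu, O2, CO2, T, GasFL; reference-value channels Lac, pH, DO. Scaling
#' weights are 0.5 for Glu and DO (their raw magnitudes dominate otherwise)
#' and 1 for the rest. Run-specific values: glucose setpoint 20 mM for runs
#' 1-4 and 19 mM for run 5; exhaust O2 21% for run 1, 19.25% otherwise;
#' exhaust CO2 1.9% (run 1), 5 then 0 (run 2), 5 (runs 3, 5), 5 then 1.9
#' (run 4). The tabulation gives no time for the mid-run CO2 setpoint
#' changes; `co2_change_day` (default 3, mid-run) supplies it.
#'
#' @param run Batch run number 1-5 (default 1).
#' @param co2_change_day Day of the CO2 setpoint step for runs 2 and 4.
#' @return Named list of [sensor_spec()] (class `sensor_specs`).
#' @export
default_sensor_specs <- function(run = 1, co2_change_day = 3) {
  if (!run %in% 1:5) stopf("`run` must be 1..5")
  glu_sp <- if (run == 5) 19 else 20
  o2_sp <- if (run == 1) 21 else 19.25
  co2_sp <- switch(run,
    `1` = 1.9,
    `2` = data.frame(from_day = c(0, co2_change_day), value = c(5, 0)),
    `3` = 5,
    `4` = data.frame(from_day = c(0, co2_change_day), value = c(5, 1.9)),
    `5` = 5)
  specs <- list(
    Glu   = sensor_spec("Glu", "SP", glu_sp, 0.5, 0.8),
    O2    = sensor_spec("O2", "SP", o2_sp, 1, 0.5),
    CO2   = sensor_spec("CO2", "SP", co2_sp, 1, 0.5),
    T     = sensor_spec("T", "SP", 37, 1, 0.5),
    GasFL = sensor_spec("GasFL", "SP", 10, 1, 0.2),
    Lac   = sensor_spec("Lac", "NSP", 10, 1, 3),
    pH    = sensor_spec("pH", "NSP", 7.1, 1, 0.35),
    DO    = sensor_spec("DO", "NSP", 72.5, 0.5, 27.5))
  structure(specs, class = "sensor_specs")
}

#' Criticality gate weight of one reading
#'
#' `w = 1` when the raw channel-unit distance of the reading from its
#' reference is greater than or equal to the critical range distance, else 0.
#' The gate always compares raw distances, whatever distance measure feeds
#' the aggregate score.
#'
#' @param spec A [sensor_spec()].
#' @param value Reading(s), channel units.
#' @param time_days Time(s) of the reading(s) (needed only for scheduled
#'   references; default 0).
#' @return Integer 0/1 vector (`NA` reading gives `NA`).
#' @export
critical_weight <- function(spec, value, time_days = 0) {
  ref <- reference_at(spec, rep_len(time_days, length(value)))
  as.integer(abs(value - ref) >= spec$critical_distance)
}

#' WWA group score over a batch run
#'
#' The weighted weighted average over one sensor group:
#' `score_t = (1/n_t) * sum_i s_i(t) * v_i * w_i(t)` with `s_i` the distance
#' of sensor `i` from its reference, `v_i` its scaling weight, `w_i` the 0/1
#' criticality gate, and `n_t` the number of *active* group sensors at `t`
#' (an inactive channel is dropped and `n` reduced, so dropout does not bias
#' the mean). With `distance = "relative"` (default) `s_i` is
#' `|value - ref| / |ref|` — dimensionless, commensurate with the shipped
#' unitless thresholds — falling back to the raw distance for a reference of
#' exactly 0; `distance = "raw"` uses channel units throughout. The gate is
#' always evaluated on the raw distance.
#'
#' @param run A [batch_run()].
#' @param specs A `sensor_specs` list, e.g. [default_sensor_specs()].
#' @param group `"SP"` or `"NSP"`.
#' @param distance `"relative"` (default) or `"raw"`.
#' @return Data frame of class `wwa_score`: `time_days`, `score`, `n_active`;
#'   attribute `contributions` (timestamps x sensors term matrix), `group`.
#'   Timestamps where no group sensor is active carry `NA` score.
#' @export
wwa_score <- function(run, specs, group = c("SP", "NSP"),
                      distance = c("relative", "raw")) {
  group <- match.arg(group)
  distance <- match.arg(distance)
  members <- Filter(function(s) s$group == group, specs)
  members <- Filter(function(s) channel_active(run, s$channel), members)
  if (!length(members))
    stopf("no active sensor in group %s", group)
  t <- run$time_days
  terms <- matrix(NA_real_, length(t), length(members),
                  dimnames = list(NULL, vapply(members, `[[`, "", "channel")))
  active <- matrix(FALSE, length(t), length(members))
  for (j in seq_along(members)) {
    sp <- members[[j]]
    v <- run$channels[[sp$channel]]
    ref <- reference_at(sp, t)
    s_raw <- abs(v - ref)
    w <- as.numeric(s_raw >= sp$critical_distance)
    s <- if (distance == "relative")
      ifelse(ref == 0, s_raw, s_raw / abs(ref)) else s_raw
    terms[, j] <- s * sp$scaling_weight * w
    active[, j] <- !is.na(v)
  }
  n_active <- rowSums(active)
  score <- ifelse(n_active > 0,
                  rowSums(terms, na.rm = TRUE) / n_active, NA_real_)
  structure(data.frame(time_days = t, score = score, n_active = n_active),
            class = c("wwa_score", "data.frame"),
            contributions = terms, group = group, distance = distance)
}

#' Threshold a WWA score into an alert stream
#'
#' Alert 1 where the score is strictly greater than the threshold, else 0
#' (shipped defaults: 0.1 for the SP group, 0.35 for NSP). Timestamps with no
#' active group sensor never alert.
#'
#' @param score A `wwa_score` from [wwa_score()].
#' @param threshold Positive unitless threshold.
#' @return An [alert_series()].
#' @export
wwa_alert <- function(score, threshold) {
  stopifnot(inherits(score, "wwa_score"))
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  alert <- !is.na(score$score) & score$score > threshold
  alert_series(score$time_days, score$score, as.integer(alert),
               paste0("WWA_", attr(score, "group")))
}
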