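#' Pipeline configuration
#'
#' All tunables of the monitoring pipeline in one validated list. The
#' defaults reproduce the shipped calibration exactly: 30 min trailing
#' window, Bollinger K = 8, alert thresholds SDI >= 3 bubbles, Bollinger
#' glucose 25% / lactate 20%, WWA SP 0.1 / NSP 0.35, fuzzy 0.45, consensus at
#' 3 of 6 sensors with a 30 min merge gap. Nothing is hard-coded downstream:
#' every smart sensor reads its parameters from here.
#'
#' @param run Batch-run number 1-5 selecting the reference/setpoint table
#'   (default 1).
#' @param window_min Trailing window for all rolling statistics, minutes.
#' @param K Bollinger band half-width in standard deviations.
#' @param estimator `"population"` or `"sample"` rolling sd.
#' @param sdi_kappas,sdi_min_count Disturbance band multipliers and the
#'   bubble count at which the SDI alert fires.
#' @param boll_glu_threshold,boll_lac_threshold Bollinger proximity alert
#'   thresholds, percent.
#' @param degenerate_policy Zero-band-width policy, see [bollinger_alert()].
#' @param wwa_sp_threshold,wwa_nsp_threshold WWA alert thresholds (unitless).
#' @param wwa_distance `"relative"` or `"raw"` distance measure, see
#'   [wwa_score()].
#' @param fuzzy_normal_full_until,fuzzy_alert_full_from Fuzzy breakpoints.
#' @param fuzzy_threshold Fuzzy alert-membership threshold.
#' @param consensus_min_sensors,consensus_merge_gap_min,consensus_min_duration_min
#'   Consensus voting parameters, see [detect_events()].
#' @param specs Sensor specifications; default [default_sensor_specs()] for
#'   `run`.
#' @param seed RNG seed recorded for provenance.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(run = 1,
                            window_min = 30,
                            K = 8,
                            estimator = "population",
                            sdi_kappas = 2:4,
                            sdi_min_count = 3,
                            boll_glu_threshold = 25,
                            boll_lac_threshold = 20,
                            degenerate_policy = "no_alert",
                            wwa_sp_threshold = 0.1,
                            wwa_nsp_threshold = 0.35,
                            wwa_distance = "relative",
                            fuzzy_normal_full_until = 0.4,
                            fuzzy_alert_full_from = 1.2,
                            fuzzy_threshold = 0.45,
                            consensus_min_sensors = 3,
                            consensus_merge_gap_min = 30,
                            consensus_min_duration_min = 0,
                            specs = default_sensor_specs(run),
                            seed = 1L) {
  cfg <- list(run = run, window_min = window_min, K = K,
              estimator = estimator, sdi_kappas = sdi_kappas,
              sdi_min_count = sdi_min_count,
              boll_glu_threshold = boll_glu_threshold,
              boll_lac_threshold = boll_lac_threshold,
              degenerate_policy = degenerate_policy,
              wwa_sp_threshold = wwa_sp_threshold,
              wwa_nsp_threshold = wwa_nsp_threshold,
              wwa_distance = wwa_distance,
              fuzzy_normal_full_until = fuzzy_normal_full_until,
              fuzzy_alert_full_from = fuzzy_alert_full_from,
              fuzzy_threshold = fuzzy_threshold,
              consensus_min_sensors = consensus_min_sensors,
              consensus_merge_gap_min = consensus_merge_gap_min,
              consensus_min_duration_min = consensus_min_duration_min,
              specs = specs, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Sensor-spec reference schedules are flattened to plain lists so the file
#' round-trips losslessly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$specs <- lapply(config$specs, function(s)
    list(channel = s$channel, group = s$group,
         reference_from_day = s$reference$from_day,
         reference_value = s$reference$value,
         scaling_weight = s$scaling_weight,
         critical_distance = s$critical_distance))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  x <- yaml::read_yaml(path)
  specs <- lapply(x$specs, function(s)
    sensor_spec(s$channel, s$group,
                data.frame(from_day = s$reference_from_day,
                           value = s$reference_value),
                s$scaling_weight, s$critical_distance))
  names(specs) <- vapply(specs, `[[`, "", "channel")
  x$specs <- NULL
  args <- x[names(x) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, c(args, list(specs = structure(
    specs, class = "sensor_specs"))))
}

#' Run all six smart sensors over a batch run
#'
#' Routes the hard-sensor channels into the smart sensors — SDI from
#' glucose + lactate, one Bollinger monitor each for glucose and lactate,
#' WWA over the SP and NSP groups, fuzzy over glucose — and assembles the
#' alert matrix. A sensor whose required channel is entirely inactive is
#' skipped with a warning; the others proceed.
#'
#' @param run A [batch_run()].
#' @param config A [pipeline_config()] (defaults match the shipped
#'   calibration).
#' @return List of class `monitor_result`: `alerts` (named list of
#'   [alert_series()]), `matrix` (an `alert_matrix` of the sensors that ran),
#'   `skipped` (character), `config`.
#' @export
monitor_run <- function(run, config = pipeline_config()) {
  stopifnot(inherits(run, "batch_run"), inherits(config, "pipeline_config"))
  alerts <- list()
  skipped <- character()
  glu_ok <- channel_active(run, "Glu")
  lac_ok <- channel_active(run, "Lac")

  if (glu_ok && lac_ok) {
    dist <- detect_disturbances(run_channel(run, "Glu"),
                                run_channel(run, "Lac"),
                                config$window_min, config$sdi_kappas,
                                config$estimator)
    alerts$SDI <- sdi_alert(dist, run$time_days, config$window_min,
                            config$sdi_min_count)
    attr(alerts$SDI, "disturbances") <- dist
  } else {
    warning("SDI skipped: glucose or lactate channel inactive",
            call. = FALSE)
    skipped <- c(skipped, "SDI")
  }

  boll <- function(channel, threshold, name) {
    if (!channel_active(run, channel)) {
      warning(sprintf("%s skipped: %s channel inactive", name, channel),
              call. = FALSE)
      skipped <<- c(skipped, name)
      return(NULL)
    }
    bollinger_monitor(run_channel(run, channel), config$window_min,
                      config$K, threshold, config$estimator,
                      config$degenerate_policy, sensor = name)
  }
  alerts$Boll_Glucose <- boll("Glu", config$boll_glu_threshold,
                              "Boll_Glucose")
  alerts$Boll_Lactate <- boll("Lac", config$boll_lac_threshold,
                              "Boll_Lactate")

  for (grp in c("SP", "NSP")) {
    nm <- paste0("WWA_", grp)
    thr <- if (grp == "SP") config$wwa_sp_threshold else
      config$wwa_nsp_threshold
    res <- tryCatch(
      wwa_alert(wwa_score(run, config$specs, grp, config$wwa_distance),
                thr),
      error = function(e) {
        warning(sprintf("%s skipped: %s", nm, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) skipped <- c(skipped, nm) else alerts[[nm]] <- res
  }

  if (glu_ok) {
    pair <- fuzzy_set_pair(config$fuzzy_normal_full_until,
                           config$fuzzy_alert_full_from)
    alerts$Fuzzy <- fuzzy_monitor(run_channel(run, "Glu"),
                                  config$specs$Glu, pair,
                                  config$fuzzy_threshold)
  } else {
    warning("Fuzzy skipped: glucose channel inactive", call. = FALSE)
    skipped <- c(skipped, "Fuzzy")
  }

  alerts <- Filter(Negate(is.null), alerts)
  if (!length(alerts)) stopf("all smart sensors were skipped")
  structure(list(alerts = alerts, matrix = alert_matrix(alerts),
                 skipped = skipped, config = config),
            class = "monitor_result")
}

#' Consensus analysis of a monitor result or alert matrix
#'
#' @param x A `monitor_result` from [monitor_run()] or an `alert_matrix`.
#' @param config A [pipeline_config()] supplying the consensus parameters.
#' @return List of class `consensus_result`: `counts`, `events`
#'   (a `consensus_events` data frame), `detected` (per-sensor coincidence
#'   counts).
#' @export
consensus_run <- function(x, config = pipeline_config()) {
  mat <- if (inherits(x, "monitor_result")) x$matrix else
    validate_alert_matrix(x)
  counts <- count_simultaneous(mat)
  events <- detect_events(counts, mat$time_days,
                          config$consensus_min_sensors,
                          config$consensus_merge_gap_min,
                          config$consensus_min_duration_min)
  structure(list(counts = counts, events = events,
                 detected = coincidence(events, mat),
                 n_events = nrow(events)),
            class = "consensus_result")
}
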