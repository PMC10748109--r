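#' Per-channel trend model for the synthetic generator
#'
#' Each channel follows
#' `value(t) = target + (initial - target) * exp(-t / tau_days) +
#' drift_per_day * t + osc_amp * sin(2 * pi * t / osc_period_days) + noise`,
#' with Gaussian noise of standard deviation `noise_sd`, inflated by
#' `prestab_noise_factor` during the pre-stabilization phase (see
#' [run_profile()]). These closed forms (exponential convergence to a
#' setpoint, linear drift, sinusoidal oscillation) are the package's own
#' modeling conventions for the qualitative batch-run dynamics: glucose
#' converging to its setpoint, lactate drifting upward, dissolved oxygen
#' declining/oscillating, pH declining from fresh-media values, temperature
#' oscillating tightly around 37 degC, stable exhaust gases and gas flow.
#'
#' @param initial Value at run start, channel units.
#' @param target Asymptotic value (setpoint/reference), channel units.
#' @param tau_days Convergence time constant, days (`Inf` = no convergence
#'   term).
#' @param drift_per_day Linear drift, channel units per day.
#' @param osc_amp,osc_period_days Sinusoidal oscillation amplitude and period.
#' @param noise_sd Gaussian noise standard deviation (`>= 0`).
#' @return List of class `channel_trend`.
#' @export
channel_trend <- function(initial, target, tau_days = Inf,
                          drift_per_day = 0, osc_amp = 0,
                          osc_period_days = 1, noise_sd = 0) {
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (tau_days <= 0) stopf("`tau_days` must be > 0 (use Inf to disable)")
  if (osc_period_days <= 0) stopf("`osc_period_days` must be > 0")
  structure(list(initial = initial, target = target, tau_days = tau_days,
                 drift_per_day = drift_per_day, osc_amp = osc_amp,
                 osc_period_days = osc_period_days, noise_sd = noise_sd),
            class = "channel_trend")
}

#' Deterministic part of a channel trend
#' @param trend A [channel_trend()].
#' @param time_days Times, days.
#' @return Numeric vector (no noise).
#' @export
trend_mean <- function(trend, time_days) {
  conv <- if (is.finite(trend$tau_days))
    (trend$initial - trend$target) * exp(-time_days / trend$tau_days)
  else rep(trend$initial - trend$target, length(time_days))
  trend$target + conv + trend$drift_per_day * time_days +
    trend$osc_amp * sin(2 * pi * time_days / trend$osc_period_days)
}

#' Synthetic batch-run profile
#'
#' The stated world a generated run emulates: a pre-stabilization phase with
#' inflated noise while channels converge to their set conditions, followed by
#' a stable perfusion phase; an activity map (e.g. an exhaust-CO2 sensor that
#' was offline for a whole run); and a schedule of injectable disturbances.
#'
#' @param run_id Run label.
#' @param duration_days Run length, days (default 6; historical runs span
#'   roughly 5-7 days).
#' @param interval_s Sampling interval, seconds (default 10, the acquisition
#'   grid; 1800 gives the 30-minute reporting grid).
#' @param prestab_hours Pre-stabilization duration, hours (default 12), with
#'   noise inflated by `prestab_noise_factor` (default 3).
#' @param channels Named list of [channel_trend()] per channel of [CHANNELS];
#'   defaults are the shipped stable-run conventions (see
#'   [default_channel_trends()]).
#' @param inactive Character vector of channels inactive for the whole run.
#' @param disturbances List of [disturbance_spec()] applied by
#'   [generate_run()] after the base run is drawn.
#' @param seed Integer RNG seed; fully determines the generated run.
#' @return List of class `run_profile`.
#' @export
run_profile <- function(run_id = "synthetic", duration_days = 6,
                        interval_s = 10, prestab_hours = 12,
                        prestab_noise_factor = 3,
                        channels = default_channel_trends(),
                        inactive = character(), disturbances = list(),
                        seed = 1L) {
  assert_scalar_number(duration_days, "duration_days", positive = TRUE)
  assert_scalar_number(interval_s, "interval_s", positive = TRUE)
  if (prestab_hours / 24 >= duration_days)
    stopf("prestabilization must be shorter than the run")
  miss <- setdiff(CHANNELS, names(channels))
  if (length(miss)) stopf("missing channel trend(s): %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(inactive, CHANNELS)
  if (length(bad)) stopf("unknown inactive channel(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(run_id = run_id, duration_days = duration_days,
                 interval_s = interval_s, prestab_hours = prestab_hours,
                 prestab_noise_factor = prestab_noise_factor,
                 channels = channels, inactive = inactive,
                 disturbances = disturbances, seed = as.integer(seed)),
            class = "run_profile")
}

#' Shipped per-channel trend conventions
#'
#' Default trends for a stable run: glucose starts at the fresh-media level
#' (25 mM) and converges to its 20 mM setpoint (tau 0.5 d, noise 0.15 mM);
#' lactate accumulates from 2 mM at +1.2 mM/day toward its 10 mM reference
#' (noise 0.12); DO declines from 90 toward 72.5 % a.s. with a daily
#' oscillation; pH declines from the fresh-media 7.4 to 7.1; temperature
#' oscillates +/-0.08 degC around 37; exhaust O2/CO2 and gas flow fluctuate
#' tightly about their setpoints. Absolute noise scales are declared
#' conventions (the qualitative dynamics fix only signs and shapes).
#'
#' @param glu_setpoint Glucose setpoint, mM (default 20; 19 for run-5-like
#'   conditions).
#' @param o2_setpoint Exhaust O2 setpoint, % (default 21).
#' @param co2_setpoint Exhaust CO2 setpoint, % (default 1.9).
#' @param gasfl_noise_sd Gas-flow noise (0 gives the constant-reading sensor
#'   seen in one historical run).
#' @return Named list of [channel_trend()].
#' @export
default_channel_trends <- function(glu_setpoint = 20, o2_setpoint = 21,
                                   co2_setpoint = 1.9,
                                   gasfl_noise_sd = 0.05) {
  list(
    T     = channel_trend(37, 37, osc_amp = 0.08, osc_period_days = 0.25,
                          noise_sd = 0.02),
    DO    = channel_trend(90, 72.5, tau_days = 0.8, osc_amp = 2,
                          osc_period_days = 1, noise_sd = 0.8),
    pH    = channel_trend(7.4, 7.1, tau_days = 1.5, noise_sd = 0.004),
    GasFL = channel_trend(10, 10, noise_sd = gasfl_noise_sd),
    Glu   = channel_trend(25, glu_setpoint, tau_days = 0.5, noise_sd = 0.15),
    Lac   = channel_trend(2, 2, drift_per_day = 1.2, noise_sd = 0.12),
    O2    = channel_trend(o2_setpoint + 0.5, o2_setpoint, tau_days = 0.3,
                          osc_amp = 0.05, osc_period_days = 0.5,
                          noise_sd = 0.05),
    CO2   = channel_trend(co2_setpoint + 1, co2_setpoint, tau_days = 0.3,
                          noise_sd = 0.05))
}

#' Disturbance specification for injection into a run
#'
#' Supported kinds:
#' * `bubble_drop` — a transitory sensing-line bubble: a simultaneous dip in
#'   glucose and lactate, `amplitude` in multiples of the local (trailing
#'   30 min) per-channel standard deviation (`units = "sigma"`, default) or
#'   in channel units (`"absolute"`).
#' * `shutdown` — a mechanical outage: glucose and lactate ramp linearly to
#'   ~0 and recover, all other channels are inactive for the interval.
#' * `channel_dropout` — one channel (argument `channel`) inactive for the
#'   interval.
#' * `temperature_dip` — an absolute dip in the temperature channel.
#'
#' @param kind One of `"bubble_drop"`, `"shutdown"`, `"channel_dropout"`,
#'   `"temperature_dip"`.
#' @param onset_days Onset time, days from run start.
#' @param duration_min Duration, minutes.
#' @param amplitude Dip amplitude (`> 0`); ignored for `shutdown` and
#'   `channel_dropout`.
#' @param units `"sigma"` or `"absolute"` (for `bubble_drop`;
#'   `temperature_dip` is always absolute).
#' @param channel Channel for `channel_dropout`.
#' @return List of class `disturbance_spec`.
#' @export
disturbance_spec <- function(kind = c("bubble_drop", "shutdown",
                                      "channel_dropout", "temperature_dip"),
                             onset_days, duration_min, amplitude = 5,
                             units = c("sigma", "absolute"),
                             channel = NULL) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  assert_scalar_number(onset_days, "onset_days")
  assert_scalar_number(duration_min, "duration_min")
  if (onset_days < 0 || duration_min < 0)
    stopf("onset and duration must be non-negative")
  if (kind %in% c("bubble_drop", "temperature_dip") && amplitude <= 0)
    stopf("`amplitude` must be > 0")
  if (kind == "channel_dropout") {
    if (is.null(channel)) stopf("`channel` required for channel_dropout")
    channel <- match.arg(channel, CHANNELS)
  }
  structure(list(kind = kind, onset_days = onset_days,
                 duration_min = duration_min, amplitude = amplitude,
                 units = units, channel = channel),
            class = "disturbance_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic batch run
#'
#' Draws the eight channels of a [run_profile()] on its uniform grid:
#' deterministic trend plus seeded Gaussian noise (inflated during
#' pre-stabilization), whole-run inactive channels as `NA`, then applies the
#' profile's disturbance schedule via [inject()]. The seed fully determines
#' the output.
#'
#' @param profile A [run_profile()].
#' @param seed Optional override of `profile$seed`.
#' @return A [batch_run()].
#' @export
generate_run <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "run_profile"))
  seed <- as.integer(seed %||% profile$seed)
  n <- floor(profile$duration_days * 86400 / profile$interval_s) + 1L
  t <- (seq_len(n) - 1L) * profile$interval_s / 86400
  prestab <- t < profile$prestab_hours / 24
  run <- with_seed(seed, {
    vals <- lapply(CHANNELS, function(ch) {
      tr <- profile$channels[[ch]]
      sd_t <- tr$noise_sd *
        ifelse(prestab, profile$prestab_noise_factor, 1)
      v <- trend_mean(tr, t) + stats::rnorm(n, 0, 1) * sd_t
      if (ch %in% profile$inactive) v[] <- NA_real_
      v
    })
    names(vals) <- CHANNELS
    batch_run(profile$run_id, t, vals,
              metadata = list(seed = seed, generator = "smartsensr"))
  })
  for (d in profile$disturbances) run <- inject(run, d)
  run
}

#' Inject a disturbance into a batch run
#'
#' Returns a new run with the disturbance of a [disturbance_spec()]
#' superimposed; the input run is not modified. A zero-duration disturbance
#' is the identity. Overlapping shutdowns are rejected.
#'
#' @param run A [batch_run()].
#' @param spec A [disturbance_spec()].
#' @return The modified [batch_run()] (metadata records the injection).
#' @export
inject <- function(run, spec) {
  stopifnot(inherits(run, "batch_run"), inherits(spec, "disturbance_spec"))
  t <- run$time_days
  end_days <- spec$onset_days + spec$duration_min / (24 * 60)
  if (spec$onset_days < t[1] || end_days > t[length(t)])
    stopf("disturbance [%g, %g] d outside run bounds", spec$onset_days,
          end_days)
  idx <- which(t >= spec$onset_days & t < end_days)
  if (!length(idx)) return(run) # zero/sub-sample duration: identity
  ch <- run$channels

  local_sd <- function(channel) {
    w <- max(2L, as.integer(round(30 * 60 / run$interval_s)))
    pre <- ch[[channel]][seq_len(max(idx[1] - 1L, 1L))]
    pre <- utils::tail(pre[!is.na(pre)], w)
    if (length(pre) < 2L)
      stopf("not enough pre-onset %s data for a sigma-scaled disturbance",
            channel)
    stats::sd(pre) * sqrt((length(pre) - 1) / length(pre))
  }

  if (spec$kind == "bubble_drop") {
    for (channel in c("Glu", "Lac")) {
      amp <- if (spec$units == "sigma")
        spec$amplitude * local_sd(channel) else spec$amplitude
      ch[[channel]][idx] <- ch[[channel]][idx] - amp
    }
  } else if (spec$kind == "temperature_dip") {
    ch[["T"]][idx] <- ch[["T"]][idx] - spec$amplitude
  } else if (spec$kind == "channel_dropout") {
    ch[[spec$channel]][idx] <- NA_real_
  } else if (spec$kind == "shutdown") {
    prev <- Filter(function(d) identical(d$kind, "shutdown"),
                   run$metadata$injected %||% list())
    for (p in prev)
      if (spec$onset_days < p$end_days && end_days > p$onset_days)
        stopf("overlapping shutdowns rejected")
    # glucose/lactate ramp to near zero and recover; other channels offline
    half <- ceiling(length(idx) / 2)
    for (channel in c("Glu", "Lac")) {
      v <- ch[[channel]]
      start_val <- v[max(idx[1] - 1L, 1L)]
      if (is.na(start_val)) start_val <- 0
      down <- seq(start_val, 0, length.out = half)
      up <- seq(0, v[min(idx[length(idx)] + 1L, length(v))],
                length.out = length(idx) - half + 1L)[-1]
      v[idx] <- c(down, up)
      ch[[channel]] <- v
    }
    for (channel in setdiff(CHANNELS, c("Glu", "Lac")))
      ch[[channel]][idx] <- NA_real_
  }
  meta <- run$metadata
  meta$injected <- c(meta$injected %||% list(),
                     list(list(kind = spec$kind,
                               onset_days = spec$onset_days,
                               end_days = end_days)))
  batch_run(run$run_id, t, ch, metadata = meta)
}

#' Shipped run profiles
#'
#' Profiles emulating the five historical batch runs' qualitative regimes:
#' * `run1_like()` — stable run, exhaust O2 setpoint 21%, CO2 1.9%.
#' * `run2_like()` — stable run, O2 19.25%, CO2 channel inactive, constant
#'   gas-flow reading.
#' * `run3_like()` — includes an ~8 h mechanical shutdown starting at day 3
#'   (glucose/lactate collapse and recovery, other sensors offline).
#' * `run4_like()` — mildly unstable: scattered sensing-line bubbles and a
#'   temperature dip.
#' * `run5_like()` — glucose setpoint 19 mM, slower stabilization and
#'   scattered bubbles.
#'
#' @param seed RNG seed (default 1).
#' @param duration_days Run length (default 6).
#' @param interval_s Sampling interval, seconds (default 10).
#' @return A [run_profile()].
#' @export
run1_like <- function(seed = 1L, duration_days = 6, interval_s = 10) {
  run_profile("run1_like", duration_days, interval_s, seed = seed)
}

#' @rdname run1_like
#' @export
run2_like <- function(seed = 1L, duration_days = 6, interval_s = 10) {
  run_profile("run2_like", duration_days, interval_s,
              channels = default_channel_trends(o2_setpoint = 19.25,
                                                co2_setpoint = 5,
                                                gasfl_noise_sd = 0),
              inactive = "CO2", seed = seed)
}

#' @rdname run1_like
#' @export
run3_like <- function(seed = 1L, duration_days = 6, interval_s = 10) {
  run_profile("run3_like", duration_days, interval_s,
              channels = default_channel_trends(o2_setpoint = 19.25,
                                                co2_setpoint = 5),
              disturbances = list(
                disturbance_spec("shutdown", onset_days = 3,
                                 duration_min = 8 * 60)),
              seed = seed)
}

#' @rdname run1_like
#' @export
run4_like <- function(seed = 1L, duration_days = 6, interval_s = 10) {
  run_profile("run4_like", duration_days, interval_s,
              channels = default_channel_trends(o2_setpoint = 19.25,
                                                co2_setpoint = 5),
              disturbances = list(
                disturbance_spec("bubble_drop", 1.5, 2, amplitude = 6),
                disturbance_spec("bubble_drop", 2.2, 2, amplitude = 5),
                disturbance_spec("bubble_drop", 4.1, 2, amplitude = 5),
                disturbance_spec("temperature_dip", 2.8, 20,
                                 amplitude = 0.6, units = "absolute")),
              seed = seed)
}

#' @rdname run1_like
#' @export
run5_like <- function(seed = 1L, duration_days = 6, interval_s = 10) {
  trends <- default_channel_trends(glu_setpoint = 19, o2_setpoint = 19.25,
                                   co2_setpoint = 5)
  trends$Glu$tau_days <- 1 # glucose takes longer to stabilize
  trends$pH$target <- 7.0  # pH below expectation at high cell numbers
  run_profile("run5_like", duration_days, interval_s, channels = trends,
              disturbances = list(
                disturbance_spec("bubble_drop", 2.5, 2, amplitude = 5),
                disturbance_spec("bubble_drop", 4.5, 2, amplitude = 5)),
              seed = seed)
}
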