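#' Detect simultaneous glucose/lactate signal disturbances
#'
#' The signal disturbance indicator (SDI) targets non-biological events —
#' transitory bubbles in the sensing line, door openings — that show up as a
#' simultaneous sharp drop in both the glucose and the lactate readings. At
#' each timestamp `i`, trailing statistics (mean, sd) over the previous
#' `window_min` minutes — *excluding* sample `i` itself — define lower bands
#' `mean - kappa * sd` per channel. A disturbance is recorded where both
#' channels fall strictly below their band for at least the smallest `kappa`;
#' its grade is set by the largest satisfied `kappa` (2 = small, 3 = medium,
#' 4 = large).
#'
#' Both channel conditions must hold at the same sample (simultaneity stands
#' in for an explicit covariance statistic); a rolling glucose/lactate
#' covariance over the same window is attached as attribute `window_cov` for
#' diagnostics only.
#'
#' @param glu,lac Glucose and lactate [channel_series()] on a common grid.
#' @param window_min Trailing window duration, minutes (default 30).
#' @param kappas Increasing integer band multipliers (default `2:4`).
#' @param estimator Standard-deviation estimator, see [rolling_stats()].
#' @return Data frame with one row per disturbance: `time_days`, `kappa`
#'   (largest satisfied multiplier), `grade` (`small`/`medium`/`large` for
#'   kappa 2/3/4), `glu_deficit`, `lac_deficit` (distance below the graded
#'   band, positive, channel units). Attributes: `window_cov` (numeric
#'   diagnostic series), `n_samples`.
#' @export
detect_disturbances <- function(glu, lac, window_min = 30, kappas = 2:4,
                                estimator = "population") {
  stopifnot(inherits(glu, "channel_series"), inherits(lac, "channel_series"))
  if (!any(glu$active)) stopf("glucose channel unavailable (all inactive)")
  if (!any(lac$active)) stopf("lactate channel unavailable (all inactive)")
  if (length(glu) != length(lac) ||
      max(abs(glu$time_days - lac$time_days)) > 1e-9)
    stopf("glucose and lactate must share the time grid")
  kappas <- sort(unique(as.numeric(kappas)))
  if (length(kappas) < 1L || any(kappas <= 0))
    stopf("`kappas` must be positive")

  sg <- rolling_stats(glu, window_min, estimator)
  sl <- rolling_stats(lac, window_min, estimator)
  n <- nrow(sg)
  lag1 <- function(v) c(NA_real_, v[-n])
  mg <- lag1(sg$mean); sdg <- lag1(sg$sd)
  ml <- lag1(sl$mean); sdl <- lag1(sl$sd)

  kmax <- rep(NA_real_, n)
  for (k in kappas) {
    hit <- glu$values < mg - sdg * k & lac$values < ml - sdl * k
    hit[is.na(hit)] <- FALSE
    kmax[hit] <- k
  }
  idx <- which(!is.na(kmax))
  grade_of <- function(k)
    c(`2` = "small", `3` = "medium", `4` = "large")[as.character(k)]
  out <- data.frame(
    time_days = glu$time_days[idx],
    kappa = kmax[idx],
    grade = unname(grade_of(kmax[idx])),
    glu_deficit = (mg[idx] - sdg[idx] * kmax[idx]) - glu$values[idx],
    lac_deficit = (ml[idx] - sdl[idx] * kmax[idx]) - lac$values[idx])
  # rolling covariance diagnostic (population), window ending at i
  nw <- attr(sg, "window_samples")
  xg <- glu$values - mean(glu$values, na.rm = TRUE)
  xl <- lac$values - mean(lac$values, na.rm = TRUE)
  covd <- data.table::frollmean(xg * xl, nw, algo = "exact") -
    data.table::frollmean(xg, nw, algo = "exact") *
    data.table::frollmean(xl, nw, algo = "exact")
  structure(out, window_cov = covd, n_samples = n,
            window_min = window_min)
}

#' SDI alert: repeated disturbances within a trailing window
#'
#' Counts disturbances ("bubbles") inside the trailing `window_min` window at
#' each grid timestamp and raises the alert when the count reaches
#' `min_count` (the shipped default threshold is "3 or more bubbles").
#'
#' @param disturbances Output of [detect_disturbances()].
#' @param time_days Time grid, days, on which to emit the alert stream.
#' @param window_min Counting window, minutes (default 30, matching the
#'   statistics window).
#' @param min_count Disturbance count at which the alert fires (default 3).
#' @return An [alert_series()] (`score` = in-window disturbance count).
#' @export
sdi_alert <- function(disturbances, time_days, window_min = 30,
                      min_count = 3) {
  assert_scalar_number(min_count, "min_count", positive = TRUE)
  w <- window_min / (24 * 60) # days
  td <- sort(disturbances$time_days)
  # count in (t - w, t]
  upper <- findInterval(time_days, td)
  lower <- findInterval(time_days - w, td)
  score <- upper - lower
  alert_series(time_days, score, as.integer(score >= min_count), "SDI")
}
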