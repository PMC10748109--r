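#' Complementary normal/alert fuzzy set pair
#'
#' Two piecewise-linear fuzzy sets over the non-negative distance of a reading
#' from its setpoint. "Normal" has full membership on
#' `[0, normal_full_until]`, falls linearly, and reaches 0 at
#' `alert_full_from`; "alert" is its exact complement (0, rising linearly to 1
#' at `alert_full_from`, 1 beyond). The shipped glucose defaults — normal
#' support `[0, 1.2]`, alert support `[0.4, Inf)` — place the breakpoints at
#' 0.4 and 1.2 mM.
#'
#' @param normal_full_until Distance up to which "normal" membership is 1
#'   (default 0.4).
#' @param alert_full_from Distance from which "alert" membership is 1
#'   (default 1.2); must exceed `normal_full_until`.
#' @return List of class `fuzzy_set_pair`.
#' @export
fuzzy_set_pair <- function(normal_full_until = 0.4, alert_full_from = 1.2) {
  assert_scalar_number(normal_full_until, "normal_full_until")
  assert_scalar_number(alert_full_from, "alert_full_from")
  if (normal_full_until < 0 || normal_full_until >= alert_full_from)
    stopf("need 0 <= normal_full_until < alert_full_from")
  structure(list(normal_full_until = normal_full_until,
                 alert_full_from = alert_full_from),
            class = "fuzzy_set_pair")
}

#' Grades of membership at a setpoint distance
#'
#' Evaluates both memberships of a [fuzzy_set_pair()] at non-negative
#' distances. They are complementary by construction:
#' `m_normal + m_alert = 1` everywhere. With the shipped glucose defaults,
#' distance 0.8 gives (0.5, 0.5), 1.0 gives (0.25, 0.75) and 1.5 gives
#' (0, 1).
#'
#' @param pair A [fuzzy_set_pair()].
#' @param distance Non-negative distance(s) from the setpoint (callers pass
#'   the absolute distance; negative input is rejected).
#' @return Data frame with columns `m_normal`, `m_alert`, both in `[0, 1]`.
#' @export
membership <- function(pair, distance) {
  stopifnot(inherits(pair, "fuzzy_set_pair"))
  if (any(distance < 0, na.rm = TRUE))
    stopf("`distance` must be non-negative (pass the absolute distance)")
  a <- pair$normal_full_until
  b <- pair$alert_full_from
  m_alert <- pmin(pmax((distance - a) / (b - a), 0), 1)
  data.frame(m_normal = 1 - m_alert, m_alert = m_alert)
}

#' Distance at which the alert membership equals a threshold
#'
#' Analytic inverse of the piecewise-linear alert membership:
#' `d* = normal_full_until + threshold * (alert_full_from -
#' normal_full_until)`.
#'
#' @inheritParams membership
#' @param threshold Membership grade in `(0, 1)`.
#' @return The distance `d*` with `m_alert(d*) = threshold`.
#' @export
fuzzy_threshold_distance <- function(pair, threshold) {
  stopifnot(inherits(pair, "fuzzy_set_pair"))
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0,1)")
  pair$normal_full_until +
    threshold * (pair$alert_full_from - pair$normal_full_until)
}

#' Threshold an alert-membership series into an alert stream
#'
#' Alert 1 where the "alert" membership grade is strictly greater than
#' `threshold` (shipped default 0.45), else 0.
#'
#' @param m_alert Alert membership grades in `[0, 1]` (`NA` = inactive, never
#'   alerts).
#' @param time_days Matching time grid, days.
#' @param threshold Membership threshold in `(0, 1)`.
#' @return An [alert_series()] (`score` = `m_alert`).
#' @export
fuzzy_alert <- function(m_alert, time_days, threshold = 0.45) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0,1)")
  alert <- !is.na(m_alert) & m_alert > threshold
  alert_series(time_days, m_alert, as.integer(alert), "Fuzzy")
}

#' One-call fuzzy stability monitor on the glucose channel
#'
#' Evaluates the fuzzy pair on `|Glu - setpoint|` and thresholds the alert
#' membership. Only the glucose definition ships enabled; other channels can
#' be monitored by calling [membership()] with their own pair.
#'
#' @param series The glucose [channel_series()].
#' @param spec The glucose [sensor_spec()] (supplies the, possibly scheduled,
#'   setpoint).
#' @param pair A [fuzzy_set_pair()] (default the shipped glucose pair).
#' @param threshold Alert-membership threshold (default 0.45).
#' @return An [alert_series()] with attribute `membership` (the full
#'   membership data frame).
#' @export
fuzzy_monitor <- function(series, spec, pair = fuzzy_set_pair(),
                          threshold = 0.45) {
  d <- abs(series$values - reference_at(spec, series$time_days))
  m <- membership(pair, d)
  out <- fuzzy_alert(m$m_alert, series$time_days, threshold)
  attr(out, "membership") <- m
  out
}
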