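# Shared fixture builders and independent brute-force oracles.
# Oracles deliberately use naive per-window recomputation so they stay
# independent of the streaming implementations they check.

make_series <- function(values, channel = "Glu", interval_s = 10) {
  n <- length(values)
  channel_series(channel, (seq_len(n) - 1) * interval_s / 86400, values)
}

# naive trailing-window mean/sd (population or sample), NA warm-up prefix
brute_rolling <- function(x, n, population = TRUE) {
  N <- length(x)
  m <- s <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    if (i < n) next
    w <- x[(i - n + 1):i]
    m[i] <- mean(w)
    v <- mean((w - mean(w))^2)
    if (!population) v <- v * n / (n - 1)
    s[i] <- sqrt(v)
  }
  list(mean = m, sd = s)
}

# naive single-pass Bollinger alert reference
brute_bollinger_alert <- function(x, n, K, threshold) {
  st <- brute_rolling(x, n)
  alert <- integer(length(x))
  for (i in seq_along(x)) {
    if (is.na(st$mean[i])) next
    up <- st$mean[i] + K * st$sd[i]
    lo <- st$mean[i] - K * st$sd[i]
    wr <- up - lo
    if (wr == 0) next # degenerate: no-alert policy
    dvp <- 100 * min(up - x[i], x[i] - lo) / wr
    if (dvp <= threshold) alert[i] <- 1L
  }
  alert
}

# naive per-window disturbance scan (window excludes current sample)
brute_disturbances <- function(g, l, n, kappas = 2:4) {
  out <- data.frame(i = integer(), kappa = numeric())
  for (i in seq_along(g)) {
    if (i <= n) next
    wg <- g[(i - n):(i - 1)]; wl <- l[(i - n):(i - 1)]
    sg <- sqrt(mean((wg - mean(wg))^2))
    sl <- sqrt(mean((wl - mean(wl))^2))
    ks <- kappas[g[i] < mean(wg) - sg * kappas &
                 l[i] < mean(wl) - sl * kappas]
    if (length(ks))
      out <- rbind(out, data.frame(i = i, kappa = max(ks)))
  }
  out
}

# random alert matrix fixture
rand_alert_matrix <- function(n, sensors = SENSORS, p = 0.05, seed = 1) {
  set.seed(seed)
  out <- data.frame(time_days = (seq_len(n) - 1) / 8640)
  for (nm in sensors) out[[nm]] <- rbinom(n, 1, p)
  out
}

default_glu_spec <- function() default_sensor_specs(1)$Glu

# tiny two-channel run on a 10 s grid for WWA tests
tiny_run <- function(n = 10, values = list()) {
  t <- (seq_len(n) - 1) * 10 / 86400
  ch <- lapply(CHANNELS, function(x) rep(NA_real_, n))
  names(ch) <- CHANNELS
  defaults <- list(T = 37, DO = 72.5, pH = 7.1, GasFL = 10, Glu = 20,
                   Lac = 10, O2 = 21, CO2 = 1.9)
  for (nm in CHANNELS) ch[[nm]] <- rep(defaults[[nm]], n)
  for (nm in names(values)) ch[[nm]] <- rep_len(values[[nm]], n)
  batch_run("tiny", t, ch)
}

# short-run profile for fast tests: scales pre-stabilization with duration
short_profile <- function(duration_days, seed, ...) {
  run_profile(duration_days = duration_days, seed = seed,
              prestab_hours = duration_days * 24 / 4, ...)
}
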