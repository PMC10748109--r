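test_that("count_simultaneous is the per-row sum and validates entries", {
  m0 <- rand_alert_matrix(50, p = 0)
  expect_equal(count_simultaneous(m0), rep(0L, 50))

  m1 <- rand_alert_matrix(10, p = 0)
  m1[4, c("SDI", "Fuzzy", "WWA_SP", "WWA_NSP")] <- 1
  expect_equal(count_simultaneous(m1)[4], 4L)

  m <- rand_alert_matrix(5000, p = 0.2, seed = 5)
  expect_equal(count_simultaneous(m),
               as.integer(rowSums(as.matrix(m[SENSORS]))))

  bad <- m1; bad$SDI[2] <- 2
  expect_error(count_simultaneous(bad), "binary")
  bad2 <- m1; bad2$SDI[2] <- NA
  expect_error(count_simultaneous(bad2), "binary")
})

test_that("detect_events finds, merges and filters above-threshold runs", {
  t <- (0:999) * 10 / 86400 # 10 s grid
  counts <- rep(0L, 1000)
  expect_equal(nrow(detect_events(counts, t)), 0)

  # one contiguous block: one event spanning it
  counts[200:260] <- 3L
  ev <- detect_events(counts, t, min_sensors = 3, merge_gap_min = 30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_days, t[200])
  expect_equal(ev$end_days, t[260])
  expect_equal(ev$peak_count, 3L)

  # second block 40 min away: separate event; 20 min away: merged
  counts2 <- counts
  counts2[260 + 240 + 1:5] <- 4L # 240 samples = 40 min gap
  ev2 <- detect_events(counts2, t, 3, merge_gap_min = 30)
  expect_equal(nrow(ev2), 2)
  counts3 <- counts
  counts3[260 + 120 + 1:5] <- 4L # 20 min gap
  ev3 <- detect_events(counts3, t, 3, merge_gap_min = 30)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$peak_count, 4L)
  expect_equal(ev3$end_days, t[260 + 125])

  # optional minimum-duration filter drops the short event
  ev4 <- detect_events(counts2, t, 3, merge_gap_min = 30,
                       min_duration_min = 5)
  expect_equal(nrow(ev4), 1)

  # interval-merge brute force on a random fixture
  set.seed(6)
  rc <- rbinom(2000, 6, 0.04)
  tt <- (0:1999) * 10 / 86400
  ev5 <- detect_events(rc, tt, 3, merge_gap_min = 10)
  hits <- which(rc >= 3)
  expect_true(all(rc[hits] >= 3))
  # every hit is inside exactly one event; events separated by >= gap
  inside <- vapply(tt[hits], function(x)
    sum(x >= ev5$start_days & x <= ev5$end_days), numeric(1))
  expect_true(all(inside == 1))
  if (nrow(ev5) > 1)
    expect_true(all(ev5$start_days[-1] - ev5$end_days[-nrow(ev5)] >=
                      10 / (24 * 60) - 1e-12))
})

test_that("detect_events is invariant under sensor-column permutation", {
  m <- rand_alert_matrix(3000, p = 0.15, seed = 7)
  ev_a <- detect_events(count_simultaneous(m), m$time_days, 3, 10)
  perm <- m[c("time_days", sample(SENSORS))]
  ev_b <- detect_events(count_simultaneous(perm), perm$time_days, 3, 10)
  expect_equal(ev_a, ev_b)
})

test_that("coincidence counts events with at least one in-event alert", {
  m <- rand_alert_matrix(500, p = 0)
  m$SDI[100:120] <- 1   # always alerting inside both events
  m$Fuzzy[300] <- 1
  events <- data.frame(start_days = m$time_days[c(100, 295)],
                       end_days = m$time_days[c(120, 305)],
                       peak_count = c(3L, 3L))
  det <- coincidence(events, m)
  expect_equal(det[["SDI"]], 1L)
  expect_equal(det[["Fuzzy"]], 1L)
  expect_equal(det[["Boll_Glucose"]], 0L)

  # randomized fixture vs per-event brute-force scan
  m2 <- rand_alert_matrix(4000, p = 0.08, seed = 8)
  ev <- detect_events(count_simultaneous(m2), m2$time_days, 2, 5)
  det2 <- coincidence(ev, m2)
  for (nm in SENSORS) {
    brute <- 0L
    for (k in seq_len(nrow(ev))) {
      idx <- which(m2$time_days >= ev$start_days[k] &
                     m2$time_days <= ev$end_days[k])
      if (any(m2[[nm]][idx] == 1)) brute <- brute + 1L
    }
    expect_equal(det2[[nm]], brute)
  }
})

test_that("summarize_coincidence reproduces the published summary table", {
  s <- reported_alert_summary()
  tab <- summarize_coincidence(s$totals, s$detected)

  expect_equal(unname(tab$sum_b),
               c(43, 16, 33, 15, 8, 7)) # per-sensor undetected totals
  expect_equal(unname(tab$pct_sum_b), c(0.75, 0.28, 0.58, 0.26, 0.14, 0.12))
  expect_equal(unname(tab$undetected["SDI", ]), c(0, 0, 13, 9, 21))
  expect_equal(sum(s$totals), 57)
  expect_equal(unname(tab$sum_s), c(3, 5, 36, 25, 53))
  expect_equal(tab$grand_undetected, 122)
  expect_equal(unname(tab$pct_sum_s), c(0.02, 0.04, 0.30, 0.20, 0.43))
  expect_equal(unname(tab$consensus_percent_sensor[
    c("Fuzzy", "WWA_NSP", "SDI", "Boll_Lactate")]), c(88, 86, 25, 42))
  expect_equal(tab$avg_consensus_sensor, 65)
  expect_equal(unname(range(tab$consensus_percent_run)), c(57, 98))
  expect_equal(tab$avg_consensus_run, 80)
})

test_that("summarize_coincidence validates and handles perfect detection", {
  s <- reported_alert_summary()
  bad <- s$detected; bad[1, 1] <- 99
  expect_error(summarize_coincidence(s$totals, bad), "lie in")

  perfect <- matrix(rep(s$totals, each = 2), 2, byrow = FALSE,
                    dimnames = list(c("A", "B"), names(s$totals)))
  tab <- summarize_coincidence(s$totals, perfect)
  expect_equal(unname(tab$sum_b), c(0, 0))
  expect_equal(unname(tab$consensus_percent_sensor), c(100, 100))
})
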