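# short grids keep the suite fast; full-length runs are exercised in
# test-acceptance.R

test_that("generation is deterministic under a fixed seed", {
  p <- short_profile(0.1, seed = 11)
  r1 <- generate_run(p)
  r2 <- generate_run(p)
  expect_identical(r1$channels, r2$channels)
  r3 <- generate_run(p, seed = 12)
  expect_false(identical(r1$channels$Glu, r3$channels$Glu))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_run(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero noise and oscillation follow the closed-form trend", {
  trends <- lapply(default_channel_trends(), function(tr) {
    tr$noise_sd <- 0; tr$osc_amp <- 0; tr
  })
  p <- run_profile(duration_days = 1, interval_s = 60, channels = trends,
                   seed = 1)
  run <- generate_run(p)
  for (ch in CHANNELS) {
    expect_equal(run$channels[[ch]],
                 trend_mean(trends[[ch]], run$time_days),
                 tolerance = 1e-12)
  }
})

test_that("post-convergence glucose mean matches the stated model", {
  # 100 seeded replicates on a coarse grid; compare the time-averaged Glu
  # over days 4-6 to the generator's closed-form expectation, within 3
  # standard errors, and to the setpoint within 0.05 mM
  reps <- 100
  means <- vapply(seq_len(reps), function(k) {
    run <- generate_run(run_profile(duration_days = 6, interval_s = 1800,
                                    seed = 1000 + k))
    sel <- run$time_days >= 4
    mean(run$channels$Glu[sel])
  }, numeric(1))
  p0 <- run_profile(duration_days = 6, interval_s = 1800, seed = 1)
  t <- generate_run(p0)$time_days
  expected <- mean(trend_mean(p0$channels$Glu, t[t >= 4]))
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - expected), 3 * se)
  expect_lt(abs(mean(means) - 20), 0.05)
  # lactate drifts upward by construction
  run <- generate_run(p0)
  expect_gt(mean(run$channels$Lac[t >= 5]), mean(run$channels$Lac[t <= 1]))
})

test_that("inject: zero-duration disturbance is the identity", {
  run <- generate_run(short_profile(0.1, seed = 2))
  out <- inject(run, disturbance_spec("bubble_drop", 0.05, 0,
                                      amplitude = 1e-9))
  expect_equal(out$channels, run$channels)
})

test_that("injected 5-sigma bubble is detected by the SDI at onset", {
  run <- generate_run(short_profile(0.5, seed = 3))
  onset <- 0.3
  out <- inject(run, disturbance_spec("bubble_drop", onset,
                                      duration_min = 2, amplitude = 5))
  d <- detect_disturbances(run_channel(out, "Glu"),
                           run_channel(out, "Lac"), 30)
  hit <- d[abs(d$time_days - onset) <= 30 / (24 * 60), ]
  expect_gte(nrow(hit), 1)
  expect_true("large" %in% hit$grade)
  expect_lte(min(abs(hit$time_days - onset)) * 8640, 1) # within one sample

  # one-channel drop alone is not a disturbance
  only_glu <- run
  idx <- which(run$time_days >= onset &
                 run$time_days < onset + 2 / (24 * 60))
  only_glu$channels$Glu[idx] <- only_glu$channels$Glu[idx] - 5 * 0.15
  d1 <- detect_disturbances(run_channel(only_glu, "Glu"),
                            run_channel(only_glu, "Lac"), 30)
  expect_false(any(abs(d1$time_days - onset) <= 2 / (24 * 60)))
})

test_that("shutdown marks other channels inactive and recovers", {
  p <- run3_like(seed = 4, duration_days = 6, interval_s = 60)
  run <- generate_run(p)
  during <- run$time_days >= 3.05 & run$time_days <= 3.25
  after <- run$time_days > 3.4
  expect_true(all(is.na(run$channels$DO[during])))
  expect_true(all(is.na(run$channels$pH[during])))
  expect_true(all(!is.na(run$channels$DO[after])))
  # glucose collapses toward 0 and recovers
  expect_lt(min(run$channels$Glu[during]), 1)
  expect_gt(mean(run$channels$Glu[after]), 15)

  # overlapping shutdowns rejected
  expect_error(inject(run, disturbance_spec("shutdown", 3.1, 60)),
               "overlapping")
  # out-of-bounds disturbances rejected
  expect_error(inject(run, disturbance_spec("bubble_drop", 5.99, 60)),
               "outside run bounds")
})

test_that("channel_dropout and temperature_dip act on their channels", {
  run <- generate_run(short_profile(0.2, seed = 5))
  out <- inject(run, disturbance_spec("channel_dropout", 0.1, 30,
                                      channel = "pH"))
  idx <- which(out$time_days >= 0.1 & out$time_days < 0.1 + 30 / 1440)
  expect_true(all(is.na(out$channels$pH[idx])))
  expect_equal(out$channels$DO, run$channels$DO)

  dip <- inject(run, disturbance_spec("temperature_dip", 0.1, 30,
                                      amplitude = 0.6, units = "absolute"))
  expect_equal(dip$channels[["T"]][idx], run$channels[["T"]][idx] - 0.6)
})

test_that("bubble recovery: 20 seeded injections, detection within window", {
  # scaled-down version of the recovery property (short runs, same physics)
  hits <- vapply(1:20, function(k) {
    run <- generate_run(short_profile(0.5, seed = 100 + k))
    onset <- 0.25
    out <- inject(run, disturbance_spec("bubble_drop", onset, 2, 5))
    d <- detect_disturbances(run_channel(out, "Glu"),
                             run_channel(out, "Lac"), 30)
    nrow(d[abs(d$time_days - onset) <= 30 / 1440, ]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
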