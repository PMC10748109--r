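test_that("critical_weight gates on raw distance at the exact boundary", {
  glu <- default_glu_spec() # setpoint 20, critical distance 0.8
  expect_equal(critical_weight(glu, 20 + 0.8), 1L)
  expect_equal(critical_weight(glu, 20 - 0.8), 1L)
  expect_equal(critical_weight(glu, 20 + 0.79), 0L)
  expect_equal(critical_weight(glu, 20), 0L)
})

test_that("scheduled references step at the configured day", {
  specs <- default_sensor_specs(run = 2, co2_change_day = 3)
  co2 <- specs$CO2
  expect_equal(reference_at(co2, c(0, 2.9, 3, 5)), c(5, 5, 0, 0))
  # gate of the stepped setpoint uses the active reference
  expect_equal(critical_weight(co2, 0.2, time_days = 4), 0L)
  expect_equal(critical_weight(co2, 0.6, time_days = 4), 1L)
})

test_that("wwa_score reduces to the single-sensor distance when gated", {
  specs <- default_sensor_specs(1)
  # all sensors exactly at reference: all gates closed, score 0
  run0 <- tiny_run()
  expect_equal(wwa_score(run0, specs, "SP")$score, rep(0, 10))
  expect_equal(wwa_score(run0, specs, "NSP")$score, rep(0, 10))

  # single active NSP sensor at twice its critical distance, v = 1, n = 1:
  # score equals the configured distance measure
  run1 <- tiny_run(values = list(Lac = 10 + 6)) # cd = 3
  run1$channels$pH[] <- NA
  run1$channels$DO[] <- NA
  sc_rel <- wwa_score(run1, specs, "NSP", "relative")
  expect_equal(sc_rel$n_active, rep(1, 10))
  expect_equal(sc_rel$score, rep(6 / 10, 10))
  sc_raw <- wwa_score(run1, specs, "NSP", "raw")
  expect_equal(sc_raw$score, rep(6, 10))
})

test_that("wwa_score matches a hand-computed two-gated SP sum", {
  specs <- default_sensor_specs(1)
  # Glu at 22 (dist 2 >= 0.8, v 0.5), GasFL at 10.5 (dist 0.5 >= 0.2, v 1);
  # T/O2/CO2 at reference. n = 5 active SP sensors.
  run <- tiny_run(values = list(Glu = 22, GasFL = 10.5))
  sc <- wwa_score(run, specs, "SP", "relative")
  expected <- ((2 / 20) * 0.5 * 1 + (0.5 / 10) * 1 * 1) / 5
  expect_equal(sc$score, rep(expected, 10))
  sc_raw <- wwa_score(run, specs, "SP", "raw")
  expect_equal(sc_raw$score, rep((2 * 0.5 + 0.5) / 5, 10))
})

test_that("inactive channels are dropped and n reduced; empty group errors", {
  specs <- default_sensor_specs(2)
  # run-2 references: O2 19.25; CO2 scheduled but offline all run
  run <- tiny_run(values = list(Glu = 22, O2 = 19.25))
  run$channels$CO2[] <- NA # whole-run dropout, as in the historical run
  sc <- wwa_score(run, specs, "SP")
  expect_equal(sc$n_active, rep(4, 10))
  expect_equal(sc$score, rep((2 / 20) * 0.5 / 4, 10))

  for (ch in c("Lac", "pH", "DO")) run$channels[[ch]][] <- NA
  expect_error(wwa_score(run, specs, "NSP"), "no active sensor")
})

test_that("WWA monotonicity, gate nesting, permutation invariance", {
  specs <- default_sensor_specs(1)
  set.seed(21)
  base <- list(T = 37.2, DO = 80, pH = 7.2, GasFL = 10.1, Glu = 21,
               Lac = 12, O2 = 21.2, CO2 = 2.1)
  run <- tiny_run(n = 4, values = base)
  for (grp in c("SP", "NSP")) {
    s0 <- wwa_score(run, specs, grp)$score[1]
    members <- names(Filter(function(s) s$group == grp, specs))
    for (ch in members) {
      # increasing any one sensor's distance never decreases the score
      run2 <- run
      ref <- reference_at(specs[[ch]], 0)
      run2$channels[[ch]][] <- ref +
        (base[[ch]] - ref) * 3 + sign(base[[ch]] - ref) * 0.5
      expect_gte(wwa_score(run2, specs, grp)$score[1], s0)
    }
  }

  # all distances strictly inside critical range: score identically 0
  inside <- tiny_run(values = list(T = 37.4, DO = 90, pH = 7.3,
                                   GasFL = 10.1, Glu = 20.7, Lac = 8.5,
                                   O2 = 21.4, CO2 = 2.2))
  expect_equal(wwa_score(inside, specs, "SP")$score, rep(0, 10))
  expect_equal(wwa_score(inside, specs, "NSP")$score, rep(0, 10))

  # permutation of the spec list leaves the score unchanged
  perm <- structure(specs[sample(names(specs))], class = "sensor_specs")
  run3 <- tiny_run(values = base)
  expect_equal(wwa_score(run3, perm, "SP")$score,
               wwa_score(run3, specs, "SP")$score)
})

test_that("wwa_alert is strictly greater-than", {
  specs <- default_sensor_specs(1)
  run <- tiny_run(values = list(Lac = 10 + 6))
  sc <- wwa_score(run, specs, "NSP") # score 0.2 everywhere
  expect_equal(sum(wwa_alert(sc, 0.2)$alert), 0)  # equal: no alert
  expect_equal(sum(wwa_alert(sc, 0.19)$alert), 10)
  # score 0 never alerts
  sc0 <- wwa_score(tiny_run(), specs, "SP")
  expect_equal(sum(wwa_alert(sc0, 1e-9)$alert), 0)
})
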