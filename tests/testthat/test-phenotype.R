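test_that("metrics recover period and offset of synthetic sinusoids", {
  t <- seq(0, 200, by = 0.05)
  Tper <- 17.3
  E1 <- 1 + 0.4 * sin(2 * pi * t / Tper)
  E2 <- 1 + 0.4 * sin(2 * pi * (t - Tper / 2) / Tper)
  met <- oscillation_metrics(t, E1, E2)
  expect_equal(met$period, Tper, tolerance = 0.01)
  expect_equal(met$phase_offset_fraction, 0.5, tolerance = 0.01)
  expect_equal(met$amplitude_1, 0.8, tolerance = 0.01)
  expect_lt(met$period_cv, 0.01)
  # quarter-period offset is recovered too
  E2q <- 1 + 0.4 * sin(2 * pi * (t - Tper / 4) / Tper)
  expect_equal(oscillation_metrics(t, E1, E2q)$phase_offset_fraction, 0.25,
               tolerance = 0.01)
})

test_that("peak detection honors the prominence threshold", {
  t <- seq(0, 50, by = 0.02)
  x <- sin(2 * pi * t / 10) + 0.05 * sin(2 * pi * t / 0.7)  # ripple
  big <- lamellosc:::find_peaks(x, prominence = 0.5)
  expect_length(big, 5)
  all_pk <- lamellosc:::find_peaks(x, prominence = 0)
  expect_gt(length(all_pk), length(big))
})

test_that("steady trajectories classify by polarity index", {
  m <- bundle_model("fig3_lv")  # K = 1.5 midpoint: bistable exclusion
  tr <- simulate_model(m, c(E1 = 0.9, E2 = 0.3), t_end = 300, n_out = 400)
  ph <- classify_trajectory(tr)
  expect_identical(ph$label, "POLARIZED_1")
  expect_gt(ph$polarity_index, 0.2)
  ph_m <- classify_trajectory(mirror_trajectory(tr))
  expect_identical(ph_m$label, "POLARIZED_2")
  # symmetric coexistence is apolar
  e4 <- ecm_submodel(1, 1, 2, 2, l_c = 1)
  tr4 <- simulate_model(e4, c(E1 = 0.3, E2 = 0.31), t_end = 300, n_out = 400)
  ph4 <- classify_trajectory(tr4)
  expect_identical(ph4$label, "APOLAR_COEXIST")
  expect_lt(abs(ph4$polarity_index), 0.05)
})

test_that("antiphase label implies negative E1-E2 correlation and
          mirror-invariant metrics", {
  m <- hybrid_model()
  tr <- simulate_model(m, default_init(m), t_end = 2000, n_out = 1500)
  ph <- classify_trajectory(tr)
  expect_identical(ph$label, "OSC_ANTIPHASE")
  expect_gte(ph$metrics$n_periods_observed, 5)
  w <- seq(length(tr$times) %/% 2, length(tr$times))
  E1 <- tr$states[w, "E1"]; E2 <- tr$states[w, "E2"]
  expect_lt(cor(E1 - mean(E1), E2 - mean(E2)), 0)
  ph_m <- classify_trajectory(mirror_trajectory(tr))
  expect_identical(ph_m$label, "OSC_ANTIPHASE")
  expect_equal(ph_m$metrics$period, ph$metrics$period, tolerance = 0.05)
})

test_that("classify_point resolves initial-condition bistability", {
  # LV Regime I: either lamellipod can win, decided by the initial bias
  e <- ecm_submodel(1, 1, 0.75, 0.75, l_c = 1)
  expect_identical(classify_point(e, t_end = 400, n_out = 400),
                   "BISTABLE_POLAR")
  # Regime IV: both initial conditions coexist
  e4 <- ecm_submodel(1, 1, 2, 2, l_c = 1)
  expect_identical(classify_point(e4, t_end = 400, n_out = 400),
                   "APOLAR_COEXIST")
  # antiphase attractor is exchange-symmetric: both runs agree
  expect_identical(classify_fast(hybrid_model()), "OSC_ANTIPHASE")
})

test_that("too-short trajectories are rejected", {
  m <- bundle_model("fig3_lv")
  tr <- simulate_model(m, c(E1 = 0.5, E2 = 0.4), t_end = 1, n_out = 4)
  expect_error(classify_trajectory(tr), "short")
})
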