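test_that("generators are deterministic under a fixed seed", {
  cfg <- gait_sim_config(n_strides = 6, seed = 123)
  a <- simulate_gait_recording(cfg)
  b <- simulate_gait_recording(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_gait_recording(gait_sim_config(n_strides = 6, seed = 124))
  expect_false(identical(a$recording$streams$accel_r$samples,
                         c2$recording$streams$accel_r$samples))
  d1 <- simulate_activity_windows(2, classes = c("walk", "sit"),
                                  windows_per_class = 2, seed = 5)
  d2 <- simulate_activity_windows(2, classes = c("walk", "sit"),
                                  windows_per_class = 2, seed = 5)
  expect_identical(d1, d2)
})

test_that("ground-truth events alternate and respect declared bounds", {
  sim <- fixture_bout
  for (leg in c("right", "left")) {
    tr <- sim$truth$events[sim$truth$events$leg == leg, ]
    expect_true(all(tr$t_contact < tr$t_off))
    expect_true(all(tr$t_off < tr$t_next_contact))
    expect_equal(tr$t_next_contact[-nrow(tr)], tr$t_contact[-1])
    expect_true(all(tr$duty_factor > 0.4 & tr$duty_factor < 0.8))
    expect_true(all(tr$stride_time >= 0.7 & tr$stride_time <= 2.2))
  }
})

test_that("config validation rejects out-of-domain parameters", {
  expect_error(gait_sim_config(stride_time = 0.5))
  expect_error(gait_sim_config(duty_factor = 0.35))
  expect_error(gait_sim_config(duty_factor = 0.75, asym = list(df_ratio = 1.13)),
               "injured duty factor")
  expect_error(gait_sim_config(asym = list(waveform_decorrelation = 1)))
})

test_that("noise-free cycle satisfies the event definitions exactly", {
  for (df in c(0.45, 0.60, 0.72)) {
    co <- remotegait:::cc_cycle_coefficients(df)
    ph <- seq(0, 1 - 1 / 8192, length.out = 8192)
    v <- eval_cycle(co, ph)
    # upward 1 g crossing at phase 0
    expect_lt(abs(v[1]), 1e-4)
    expect_gt(v[2] - v[1], 0)
    # fundamental minimum at the duty-factor phase
    f1 <- 2 * Re(co[2] * exp(2i * pi * ph))
    expect_equal(ph[which.min(f1)], df, tolerance = 2e-3)
    # distinct swing trough below stance values
    expect_lt(min(v), -0.2)
    expect_gt(max(v[ph < df]), 0.05)
  }
})

test_that("decorrelation mixing hits the requested waveform asymmetry", {
  g <- seq(0, 1, length.out = 101)
  for (d in c(0.05, 0.1, 0.3)) {
    lam <- remotegait:::solve_decorr_lambda(d)
    w <- remotegait:::ap_cycle(g)
    a <- (1 - stats::cor(w, w + lam * remotegait:::decorr_cycle(g))) / 2
    expect_equal(a, d, tolerance = 1e-6)
  }
  expect_equal(remotegait:::solve_decorr_lambda(0), 0)
})

test_that("clipping injection is detected and standing trials verify", {
  simc <- simulate_gait_recording(
    gait_sim_config(n_strides = 6, clipping = TRUE, seed = 3))
  expect_true(detect_clipping(simc$recording$streams$accel_r$samples, 16))
  cal <- simulate_standing_calibration(15, seed = 2)
  expect_equal(sqrt(sum(cal$cc_axis^2)), 1, tolerance = 1e-12)
})

test_that("simulated day aligns walking spans to the window grid", {
  day <- simulate_day(walk_bouts = 2, bout_s = 40, rest_s = 24,
                      cfg = gait_sim_config(n_strides = 30, seed = 8))
  expect_equal(day$truth$walking_time_s, 80)
  expect_true(all(day$truth$walk_spans %% 4 == 0))
  dur <- nrow(day$recording$streams$accel_r$samples) / 31.25
  expect_equal(dur, 2 * (40 + 24))
  ev <- day$truth$events
  expect_true(all(ev$t_contact >= day$truth$walk_spans[1, 1]))
})
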