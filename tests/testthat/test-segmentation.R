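test_that("cadence estimation finds known tones and rejects noise", {
  fs <- 31.25
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 1.0 * t) + 0.5 * sin(2 * pi * 2.0 * t)
  cad <- estimate_cadence(x, fs)
  expect_equal(cad$f_stride, 1.0, tolerance = 0.05)
  expect_equal(cad$f_step, 2.0, tolerance = 0.1)
  set.seed(10)
  expect_error(estimate_cadence(rnorm(60 * fs), fs), "cadence error")
  expect_error(estimate_cadence(x[1:100], fs), "shorter than 8 s")
})

test_that("cadence matches the simulator's stride time", {
  sim <- simulate_gait_recording(gait_sim_config(stride_time = 1.10,
                                                 n_strides = 16, seed = 2))
  s <- sim$recording$streams$accel_r
  cc <- drop(s$samples %*% sim$calibration$right$cc_axis)
  cad <- estimate_cadence(cc, s$rate)
  expect_equal(cad$f_stride, 1 / 1.10, tolerance = 0.05)
  expect_equal(cad$f_step, 2 / 1.10, tolerance = 0.15)
})

test_that("event detection on a 1 g sinusoid finds analytic crossings", {
  fs <- 31.25
  t <- seq(0, 24, by = 1 / fs)
  cc <- 1 + 0.3 * sin(2 * pi * t / 1.2)
  cad <- list(f_stride = 1 / 1.2, f_step = 2 / 1.2)
  ev <- detect_gait_events(cc, fs, cad)
  # minima of the sinusoid at t = 0.9 + 1.2 k; crossings at t = 1.2 k
  interior <- ev$foot_offs > 2 & ev$foot_offs < 22
  offs <- ev$foot_offs[interior]
  expect_gt(length(offs), 12)
  expect_lt(max(abs((offs - 0.9) %% 1.2) %% 1.2 * ((abs((offs - 0.9) %% 1.2) < 0.6) * 2 - 1)), 0.05)
  contacts <- ev$foot_contacts[ev$foot_contacts > 2 & ev$foot_contacts < 22]
  resid <- contacts %% 1.2
  resid <- pmin(resid, 1.2 - resid)
  expect_lt(max(resid), 0.05)
  # one foot off per period
  expect_equal(round(diff(offs) / 1.2), rep(1, length(offs) - 1))
})

test_that("a constant 1 g signal yields no events", {
  ev <- detect_gait_events(rep(1, 400), 31.25,
                           list(f_stride = 1, f_step = 2))
  expect_length(ev$foot_offs, 0)
  expect_length(ev$foot_contacts, 0)
})

test_that("event times are invariant to time reversal of a symmetric signal", {
  fs <- 31.25
  t <- seq(0, 24, by = 1 / fs)
  cc <- 1 + 0.3 * cos(2 * pi * t / 1.2)  # symmetric about t = 0 grid
  cad <- list(f_stride = 1 / 1.2, f_step = 2 / 1.2)
  ev_f <- detect_gait_events(cc, fs, cad)
  ev_r <- detect_gait_events(rev(cc), fs, cad)
  # foot offs (filtered minima) must mirror: t -> T - t
  T_end <- (length(cc) - 1) / fs
  mir <- sort(T_end - ev_r$foot_offs)
  keep <- ev_f$foot_offs > 2 & ev_f$foot_offs < 22
  for (x in ev_f$foot_offs[keep]) {
    expect_lt(min(abs(mir - x)), 1 / fs)
  }
})

test_that("stride segmentation applies constraints with reasons", {
  ev <- list(foot_contacts = c(0, 1.2), foot_offs = c(0.78))
  seg <- segment_strides(ev)
  expect_equal(seg$retained$stride_time, 1.2)
  expect_equal(seg$retained$duty_factor, 0.65)
  # stride time above 1.57 s rejected
  seg2 <- segment_strides(list(foot_contacts = c(0, 2.0), foot_offs = 1.0))
  expect_false(seg2$strides$retained)
  expect_equal(seg2$strides$reason, "stride_time_out_of_bounds")
  # duty factor below 0.44 rejected
  seg3 <- segment_strides(list(foot_contacts = c(0, 1.0), foot_offs = 0.40))
  expect_false(seg3$strides$retained)
  expect_equal(seg3$strides$reason, "duty_factor_out_of_bounds")
  # boundary values retained (closed bounds)
  seg4 <- segment_strides(list(foot_contacts = c(0, 0.91), foot_offs = 0.44 * 0.91))
  expect_true(seg4$strides$retained)
  # empty events -> empty tables, no error
  seg5 <- segment_strides(list(foot_contacts = numeric(0), foot_offs = numeric(0)))
  expect_equal(nrow(seg5$strides), 0)
})

test_that("retained strides tile the bout without overlap", {
  sim <- fixture_bout
  r <- stride_recovery(sim)
  s <- sim$recording$streams$accel_r
  cc <- drop(s$samples %*% sim$calibration$right$cc_axis)
  det <- segment_strides(detect_gait_events(cc, s$rate, r$cadence))$retained
  expect_true(all(diff(det$t_contact) > 0))
  # consecutive strides share boundaries: next_contact(i) == contact(i+1)
  expect_equal(det$t_next_contact[-nrow(det)], det$t_contact[-1],
               tolerance = 1e-9)
})
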