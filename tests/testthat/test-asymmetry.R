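test_that("EMG envelope follows the rectified-mean of a tone", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)
  A <- 0.8
  x <- A * sin(2 * pi * 50 * t)
  env <- emg_envelope(x, fs)
  core <- round(length(env) * 0.2):round(length(env) * 0.8)
  expect_equal(mean(env[core]), 2 * A / pi, tolerance = 0.1 * 2 * A / pi)
  # rectification symmetry and null input
  expect_equal(emg_envelope(-x, fs), env, tolerance = 1e-9)
  expect_equal(emg_envelope(rep(0, 2000), fs), rep(0, 2000))
  expect_true(all(env >= 0))
  expect_error(emg_envelope(x[1:50], fs), "envelope error")
  expect_error(emg_envelope(x, 50), "at least 100")
})

test_that("stride time normalization hits the 101-point contract", {
  t <- seq(0, 1.2, by = 1 / 250)
  out <- normalize_stride_waveforms(
    list(const = list(t = t, x = rep(3, length(t))),
         ramp = list(t = t, x = t),
         sine = list(t = t, x = sin(2 * pi * t / 1.2))),
    0, 1.2)
  expect_length(out$const, 101)
  expect_equal(out$const, rep(3, 101))
  expect_equal(out$ramp, seq(0, 1.2, length.out = 101), tolerance = 1e-9)
  # one full cycle across the grid: ends meet
  expect_equal(out$sine[1], out$sine[101], tolerance = 1e-6)
  expect_equal(out$sine[26], 1, tolerance = 1e-3)
})

test_that("discrete asymmetry is |I - H| / |H| with a zero guard", {
  expect_equal(discrete_asymmetry(0.6, 0.6), 0)
  expect_equal(discrete_asymmetry(0.15, 0.10), 0.5)
  expect_equal(discrete_asymmetry(0.10, -0.10), 2)
  expect_error(discrete_asymmetry(0.1, 0), "zero")
  expect_error(discrete_asymmetry(NaN, 1), "non-finite")
})

test_that("waveform asymmetry spans [0, 1] with correlation semantics", {
  g <- seq(0, 1, length.out = 101)
  w <- sin(2 * pi * g)
  expect_equal(waveform_asymmetry(w, w), 0)
  expect_equal(waveform_asymmetry(w, -w), 1)
  expect_equal(waveform_asymmetry(sin(2 * pi * g), cos(2 * pi * g)), 0.5,
               tolerance = 0.02)
  expect_error(waveform_asymmetry(rep(1, 101), w), "zero-variance")
  # affine invariance and boundedness
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(101); b <- rnorm(101)
    v <- waveform_asymmetry(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(waveform_asymmetry(2.5 * a + 3, b), v, tolerance = 1e-12)
  }
})

make_stride <- function(df = 0.6, emg, CC, AP, ML) {
  g <- seq(0, 1, length.out = 101)
  list(emg = emg(g), CC = CC(g), AP = AP(g), ML = ML(g), duty_factor = df)
}

test_that("mirrored legs give all-zero indices; composite is the mean", {
  g <- seq(0, 1, length.out = 101)
  mk <- function() make_stride(0.6,
    function(g) 0.5 + 0.3 * sin(2 * pi * g),
    function(g) 1 + 0.2 * cos(2 * pi * g),
    function(g) 0.2 * sin(2 * pi * g + 1),
    function(g) 0.1 * cos(4 * pi * g))
  rec <- bout_asymmetry(list(mk(), mk()), list(mk(), mk()))
  for (nm in asymmetry_index_names()) expect_equal(rec[[nm]], 0)
  expect_equal(rec$composite, 0)
  # composite = mean of the seven to machine precision
  rec2 <- rec
  vals <- c(0.1, 0.2, 0.3, 0.05, 0.15, 0.25, 0.35)
  for (i in seq_along(vals)) rec2[[asymmetry_index_names()[i]]] <- vals[i]
  expect_equal(mean(vals), mean(unlist(rec2[asymmetry_index_names()])),
               tolerance = 1e-12)
  expect_error(bout_asymmetry(list(mk()), list(mk(), mk())), "at least two")
})

test_that("simulator DF asymmetry is recovered through the analysis path", {
  cfg <- gait_sim_config(stride_time = 1.10, duty_factor = 0.55,
                         n_strides = 16, asym = list(df_ratio = 1.13),
                         seed = 9)
  sim <- simulate_gait_recording(cfg)
  out <- analyze_gait_bout(sim$recording, sim$calibration)
  expect_lt(abs(out$record$a_df - 0.13), 0.03)
})

test_that("outlier removal drops gross composite outliers per subject", {
  rec <- data.frame(subject_id = "S1", composite = c(rep(0.2, 9), 5.0),
                    bout_id = 1:10)
  out <- remove_outlier_asymmetries(rec)
  expect_equal(nrow(out), 9)
  expect_false(5.0 %in% out$composite)
  expect_equal(attr(out, "n_removed"), 1)
  # identical values: nothing removed
  rec2 <- data.frame(subject_id = "S1", composite = rep(0.3, 6), bout_id = 1:6)
  expect_equal(nrow(remove_outlier_asymmetries(rec2)), 6)
  # small samples pass through
  rec3 <- data.frame(subject_id = "S1", composite = c(0.1, 0.2, 9), bout_id = 1:3)
  expect_equal(nrow(remove_outlier_asymmetries(rec3)), 3)
  # per-subject independence
  rec4 <- rbind(rec, transform(rec2, subject_id = "S2"))
  out4 <- remove_outlier_asymmetries(rec4)
  expect_equal(sum(out4$subject_id == "S2"), 6)
})
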