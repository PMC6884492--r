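test_that("CC axis estimation recovers gravity and guards against motion", {
  n <- 100
  const <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  expect_equal(estimate_cc_axis(const), c(0, 0, 1))
  tilted <- matrix(rep(c(0, 0.6, 0.8), each = n), n, 3)
  expect_equal(estimate_cc_axis(tilted), c(0, 0.6, 0.8))
  set.seed(1)
  moving <- const + matrix(rnorm(3 * n, sd = 0.5), n, 3)
  expect_error(estimate_cc_axis(moving), "calibration error")
  expect_error(estimate_cc_axis(0.5 * const), "calibration error")  # norm
})

test_that("simulated standing trials recover the CC axis to spec accuracy", {
  ang <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi
  for (tilt in c(0, 20)) {
    cal <- simulate_standing_calibration(tilt, seed = 7)
    est <- estimate_cc_axis(cal$accel)
    expect_lt(ang(est, cal$cc_axis), 2)
  }
  cal0 <- simulate_standing_calibration(10, seed = 1, noise_sd = 0)
  expect_equal(estimate_cc_axis(cal0$accel), cal0$cc_axis, tolerance = 1e-12)
})

test_that("AP axis via transverse PCA recovers a known direction", {
  set.seed(2)
  cc <- c(0, 0, 1)
  # AP at 30 degrees in the transverse (x, y) plane
  ap_true <- c(cos(pi / 6), sin(pi / 6), 0)
  t <- seq(0, 4, by = 1 / 31.25)
  sig <- outer(0.4 * sin(2 * pi * t), ap_true) +
    matrix(rnorm(length(t) * 3, sd = 0.02), length(t), 3)
  # add positive skew along AP so the sign convention fires
  sig <- sig + outer(0.15 * pmax(sin(2 * pi * t), 0), ap_true)
  fr <- estimate_ap_ml_axes(sig, cc)
  expect_false(fr$indeterminate)
  ang <- acos(abs(sum(fr$ap * ap_true))) * 180 / pi
  expect_lt(ang, 5)
  # orthonormal right-handed triad
  expect_equal(sum(fr$ap * fr$cc), 0, tolerance = 1e-9)
  expect_equal(sqrt(sum(fr$ap^2)), 1, tolerance = 1e-9)
  expect_equal(fr$ml, remotegait:::cross3(fr$cc, fr$ap), tolerance = 1e-12)
})

test_that("degenerate transverse variance flags the window", {
  cc <- c(0, 0, 1)
  quiet <- matrix(rep(c(0, 0, 1), each = 50), 50, 3)
  fr <- estimate_ap_ml_axes(quiet, cc)
  expect_true(fr$indeterminate)
  prev <- list(ap = c(0, 1, 0))
  fr2 <- estimate_ap_ml_axes(quiet, cc, prev = prev)
  expect_true(fr2$indeterminate)
  expect_equal(fr2$ap, c(0, 1, 0))
})

test_that("anatomical projection preserves norms and is frame-consistent", {
  set.seed(3)
  raw <- matrix(rnorm(300), 100, 3)
  cc <- remotegait:::unit(c(0.2, -0.1, 0.97))
  fr <- estimate_ap_ml_axes(raw, cc)
  anat <- to_anatomical(raw, fr)
  expect_equal(sqrt(rowSums(anat^2)), sqrt(rowSums(raw^2)), tolerance = 1e-9)
  expect_equal(to_anatomical(matrix(c(0, 0, 1), 1),
                             list(cc = c(0, 0, 1), ap = c(1, 0, 0),
                                  ml = c(0, 1, 0)))[1, ],
               c(CC = 1, AP = 0, ML = 0))
  # rotating data and axes together leaves channels unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr_rot <- list(cc = drop(R %*% fr$cc), ap = drop(R %*% fr$ap),
                 ml = drop(R %*% fr$ml))
  expect_equal(to_anatomical(raw %*% t(R), fr_rot), anat, tolerance = 1e-9)
})
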