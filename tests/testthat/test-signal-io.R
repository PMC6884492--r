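make_rec <- function(dur = 60, fs_a = 31.25, fs_e = 250) {
  na <- round(dur * fs_a); ne <- round(dur * fs_e)
  bilateral_recording(
    sensor_stream(matrix(rnorm(na * 3), na, 3), fs_a, "right", "accel"),
    sensor_stream(matrix(rnorm(na * 3), na, 3), fs_a, "left", "accel"),
    sensor_stream(matrix(rnorm(ne), ne, 1), fs_e, "right", "semg"),
    sensor_stream(matrix(rnorm(ne), ne, 1), fs_e, "left", "semg"))
}

test_that("CSV round trip is lossless and metadata survives", {
  sim <- fixture_bout
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, path)
  rec2 <- load_recording(path)
  for (nm in names(sim$recording$streams)) {
    expect_equal(rec2$streams[[nm]]$samples, sim$recording$streams[[nm]]$samples,
                 tolerance = 1e-12)
    expect_equal(rec2$streams[[nm]]$rate, sim$recording$streams[[nm]]$rate)
  }
  expect_equal(rec2$subject_id, sim$recording$subject_id)
})

test_that("load_recording raises format and sampling errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(make_rec(10), path)
  df <- utils::read.csv(path)
  # drop left sEMG -> format error
  utils::write.csv(df[df$stream != "semg_l", ], path, row.names = FALSE)
  expect_error(load_recording(path), "missing stream")
  # corrupt timestamps -> sampling error
  df2 <- df
  bad <- which(df2$stream == "accel_r")[10]
  df2$t[bad] <- df2$t[bad] + 0.02
  utils::write.csv(df2, path, row.names = FALSE)
  file.remove(paste0(path, ".meta.json"))
  expect_error(load_recording(path, layout = list(accel_r = list(rate = 31.25))),
               "sampling error")
  expect_error(load_recording(tempfile()), "not found")
})

test_that("window partitioning follows the floor(duration/4) rule", {
  expect_length(partition_windows(make_rec(60)), 15)
  expect_length(partition_windows(make_rec(10)), 2)
  expect_length(partition_windows(make_rec(3.9)), 0)
  # property: random durations
  for (dur in runif(8, 4, 40)) {
    wins <- partition_windows(make_rec(dur))
    expect_length(wins, floor(dur / 4))
    expect_true(all(vapply(wins, function(w) nrow(w$accel_R), numeric(1)) ==
                      round(4 * 31.25)))
    starts <- vapply(wins, `[[`, numeric(1), "start")
    expect_equal(diff(starts), rep(4, length(wins) - 1))
  }
})

test_that("clipping detector applies the run-length rule symmetrically", {
  seg <- matrix(rnorm(100, sd = 1), ncol = 1)
  expect_false(detect_clipping(seg, 16))
  seg[40:44] <- 16
  expect_true(detect_clipping(seg, 16))
  expect_true(detect_clipping(-seg, 16))  # sign invariance
  seg2 <- matrix(rnorm(100), ncol = 1)
  seg2[50] <- -16
  expect_false(detect_clipping(seg2, 16, k = 3))
  seg2[50:51] <- -16
  expect_false(detect_clipping(seg2, 16, k = 3))
  seg2[50:52] <- -16
  expect_true(detect_clipping(seg2, 16, k = 3))
  expect_false(detect_clipping(matrix(15 * sin(1:50), ncol = 1), 16))
  expect_false(detect_clipping(matrix(1:5, ncol = 1), Inf))
})
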