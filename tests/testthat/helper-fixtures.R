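# Shared fixtures, built once per test run. Sizes are kept small so the
# whole suite stays well inside the runtime budget.

# labelled activity features + trained classifier (used across files)
fixture_activity <- simulate_activity_windows(8, seed = 3)
fixture_feature_cols <- c(canonical_features(), "noise_a", "noise_b")
fixture_model <- local({
  feats <- select_features(fixture_activity[fixture_feature_cols],
                           fixture_activity$label)
  train_classifier(fixture_activity[fixture_feature_cols],
                   fixture_activity$label,
                   feature_subset = as.character(feats))
})

# one clean neutral walking bout + truth
fixture_bout <- simulate_gait_recording(
  gait_sim_config(stride_time = 1.10, duty_factor = 0.60,
                  n_strides = 16, seed = 42))

# match detected strides against ground truth; returns recovery stats
stride_recovery <- function(sim, leg = "right") {
  s <- sim$recording$streams[[paste0("accel_", substr(leg, 1, 1))]]
  cc_axis <- sim$calibration[[leg]]$cc_axis
  cc <- drop(s$samples %*% cc_axis)
  cad <- estimate_cadence(cc, s$rate)
  ev <- detect_gait_events(cc, s$rate, cad)
  det <- segment_strides(ev)$retained
  tr <- sim$truth$events[sim$truth$events$leg == leg, , drop = FALSE]
  st_err <- c()
  df_err <- c()
  hits <- 0
  for (k in seq_len(nrow(tr))) {
    j <- which(abs(det$t_contact - tr$t_contact[k]) < 0.25 * tr$stride_time[k])
    if (length(j)) {
      j <- j[which.min(abs(det$t_contact[j] - tr$t_contact[k]))]
      hits <- hits + 1
      st_err <- c(st_err, abs(det$stride_time[j] - tr$stride_time[k]))
      df_err <- c(df_err, abs(det$duty_factor[j] - tr$duty_factor[k]))
    }
  }
  list(recovery = hits / nrow(tr),
       st_err = mean(st_err), df_err = mean(df_err),
       cadence = cad, n_true = nrow(tr), n_det = nrow(det))
}
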