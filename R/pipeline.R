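# Subject-day pipeline: calibration -> walking-bout identification ->
# stride segmentation -> asymmetry analysis, with a per-window audit log.

#' Pipeline configuration
#'
#' Defaults are the published operating points: posterior threshold 0.8,
#' stride time 0.91-1.57 s, duty factor 0.44-0.73, DBI threshold 2, 6 Hz
#' kinematic lowpass, 5 Hz event filter, 4-s windows, 2-window (8 s)
#' minimum bouts with at least 2 retained strides per leg.
#'
#' @param prob_threshold Walking posterior threshold.
#' @param st_bounds,df_bounds Stride-time (s) / duty-factor constraints.
#' @param dbi_threshold Davies-Bouldin selection threshold.
#' @param kin_lowpass_hz Kinematic lowpass cutoff (Hz).
#' @param event_filter_hz Contact-detection lowpass cutoff (Hz).
#' @param emg_band,envelope_hz sEMG envelope recipe (Hz).
#' @param clip_k,clip_eps Clipping run length and rail tolerance fraction.
#' @param window_s Analysis window length (s).
#' @param min_bout_windows Minimum consecutive walking windows per bout.
#' @param min_strides_per_leg Minimum retained strides per leg and bout.
#' @param injured_leg `"right"` or `"left"`.
#' @param emg_norm_quantile Per-leg per-day envelope normalization
#'   quantile (default 0.95).
#' @param seed Seed for any stochastic step.
#' @param bin_minutes,bin_enabled Optional time-of-day binning of the
#'   composite score.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(prob_threshold = 0.8,
                            st_bounds = c(0.91, 1.57),
                            df_bounds = c(0.44, 0.73),
                            dbi_threshold = 2,
                            kin_lowpass_hz = 6,
                            event_filter_hz = 5,
                            emg_band = c(20, 100),
                            envelope_hz = 6,
                            clip_k = 3, clip_eps = 0.01,
                            window_s = 4,
                            min_bout_windows = 2,
                            min_strides_per_leg = 2,
                            injured_leg = "right",
                            emg_norm_quantile = 0.95,
                            seed = 1,
                            bin_minutes = 15, bin_enabled = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Segment strides and build time-normalized per-stride waveforms for one
# walking bout (both legs). Returns NULL per_leg with a drop reason when
# the bout fails cadence estimation or the minimum-stride rule.
process_bout <- function(rec, cc, t_start, t_end, cfg,
                         prev_frame = list(right = NULL, left = NULL)) {
  rate_a <- rec$streams$accel_r$rate
  stream_of <- list(right = rec$streams$accel_r, left = rec$streams$accel_l)
  emg_of <- list(right = rec$streams$semg_r, left = rec$streams$semg_l)
  per_leg <- list()
  stride_rows <- list()
  drop_reason <- NULL
  for (leg in c("right", "left")) {
    sl <- slice_stream(stream_of[[leg]], t_start, t_end)
    frame <- estimate_ap_ml_axes(sl$samples, cc[[leg]], prev = prev_frame[[leg]])
    prev_frame[[leg]] <- frame
    anat <- to_anatomical(sl$samples, frame)
    cadence <- tryCatch(estimate_cadence(anat[, "CC"], rate_a),
                        error = function(e) NULL)
    if (is.null(cadence)) { drop_reason <- "dropped:cadence_error"; break }
    events <- detect_gait_events(anat[, "CC"], rate_a, cadence, t0 = sl$t[1],
                                 event_filter_hz = cfg$event_filter_hz)
    seg <- segment_strides(events, cfg$st_bounds, cfg$df_bounds)
    if (nrow(seg$strides)) {
      stride_rows[[length(stride_rows) + 1]] <- cbind(leg = leg, seg$strides)
    }
    if (nrow(seg$retained) < cfg$min_strides_per_leg) {
      drop_reason <- "dropped:too_few_strides"
      break
    }
    lp6 <- function(x) filtfilt_zero_phase(
      butter_design(4, cfg$kin_lowpass_hz, rate_a), x)
    kin <- list(CC = lp6(anat[, "CC"]), AP = lp6(anat[, "AP"]),
                ML = lp6(anat[, "ML"]))
    es <- slice_stream(emg_of[[leg]], t_start, t_end)
    env <- emg_envelope(es$samples[, 1], emg_of[[leg]]$rate,
                        band = cfg$emg_band, envelope_hz = cfg$envelope_hz)
    strides <- lapply(seq_len(nrow(seg$retained)), function(k) {
      srow <- seg$retained[k, ]
      ch <- normalize_stride_waveforms(
        list(emg = list(t = es$t, x = env),
             CC = list(t = sl$t, x = kin$CC),
             AP = list(t = sl$t, x = kin$AP),
             ML = list(t = sl$t, x = kin$ML)),
        srow$t_contact, srow$t_next_contact)
      ch$duty_factor <- srow$duty_factor
      ch
    })
    per_leg[[leg]] <- strides
  }
  strides_df <- if (length(stride_rows)) do.call(rbind, stride_rows) else
    data.frame()
  list(per_leg = if (is.null(drop_reason)) per_leg else NULL,
       strides = strides_df, drop_reason = drop_reason,
       prev_frame = prev_frame)
}

#' Analyze one recording as a single walking bout
#'
#' Convenience path that skips classification: treats the whole recording
#' span as one walking bout, segments strides on both legs, normalizes
#' waveforms (per-leg sEMG normalization from this bout's retained
#' strides) and computes the asymmetry record.
#'
#' @param rec A [bilateral_recording()] containing continuous walking.
#' @param calibration Per-leg standing trials (as in [run_pipeline()]).
#' @param cfg A [pipeline_config()].
#' @return List with `record` (an `asymmetry_record` or `NULL` with
#'   `drop_reason`), and the `strides` table.
#' @export
analyze_gait_bout <- function(rec, calibration, cfg = pipeline_config()) {
  cc <- list(right = estimate_cc_axis(calibration$right$accel),
             left = estimate_cc_axis(calibration$left$accel))
  t0 <- max(vapply(rec$streams, function(s) s$t0, numeric(1)))
  t1 <- min(vapply(rec$streams, function(s) s$t0 + stream_duration(s), numeric(1)))
  pb <- process_bout(rec, cc, t0, t1, cfg)
  if (!is.null(pb$drop_reason)) {
    return(list(record = NULL, drop_reason = pb$drop_reason,
                strides = pb$strides))
  }
  injured <- cfg$injured_leg
  healthy <- setdiff(c("right", "left"), injured)
  norm_leg <- function(leg) {
    v <- unlist(lapply(pb$per_leg[[leg]], `[[`, "emg"))
    q <- stats::quantile(v, cfg$emg_norm_quantile, names = FALSE)
    lapply(pb$per_leg[[leg]], function(s) { s$emg <- s$emg / q; s })
  }
  rec_out <- bout_asymmetry(norm_leg(injured), norm_leg(healthy),
                            bout_id = 1L, subject_id = rec$subject_id,
                            timestamp = t0)
  list(record = rec_out, drop_reason = NULL, strides = pb$strides)
}

slice_stream <- function(s, t0, t1) {
  i0 <- max(1L, round((t0 - s$t0) * s$rate) + 1L)
  i1 <- min(nrow(s$samples), round((t1 - s$t0) * s$rate))
  list(samples = s$samples[i0:i1, , drop = FALSE],
       t = s$t0 + (seq(i0, i1) - 1) / s$rate)
}

#' Run the full gait-analysis pipeline on one subject-day
#'
#' @param rec A [bilateral_recording()].
#' @param model A trained `walk_classifier`.
#' @param cfg A [pipeline_config()].
#' @param calibration List with `right`/`left` standing-trial elements,
#'   each containing an `accel` matrix (as produced by the simulator's
#'   `calibration` slot).
#' @return List: `summary` (subject-day totals and daily index means),
#'   `records` (per-bout asymmetry data frame, post outlier removal),
#'   `records_raw`, `strides` (per-stride table), `audit` (per-window
#'   accounting), `bouts`.
#' @export
run_pipeline <- function(rec, model, cfg = pipeline_config(), calibration) {
  cc <- list(right = estimate_cc_axis(calibration$right$accel),
             left = estimate_cc_axis(calibration$left$accel))
  rate_a <- rec$streams$accel_r$rate
  windows <- partition_windows(rec, cfg$window_s)
  n_win <- length(windows)
  audit <- data.frame(window_index = seq_len(n_win),
                      status = rep("not_walking", n_win),
                      stringsAsFactors = FALSE)
  if (n_win == 0) {
    return(list(summary = day_summary(list(walking_time_s = 0), data.frame(),
                                      data.frame(), cfg, rec),
                records = data.frame(), records_raw = data.frame(),
                strides = data.frame(), audit = audit, bouts = list()))
  }
  fm <- window_feature_matrix(windows, cc$right, cc$left, rate_a)
  pred <- predict(model, fm)
  clipped <- vapply(windows, function(w) {
    detect_clipping(w$accel_R, rec$streams$accel_r$range_limit, cfg$clip_k, cfg$clip_eps) ||
      detect_clipping(w$accel_L, rec$streams$accel_l$range_limit, cfg$clip_k, cfg$clip_eps) ||
      detect_clipping(w$semg_R, rec$streams$semg_r$range_limit, cfg$clip_k, cfg$clip_eps) ||
      detect_clipping(w$semg_L, rec$streams$semg_l$range_limit, cfg$clip_k, cfg$clip_eps)
  }, logical(1))
  bw <- build_walking_bouts(pred$label == model$positive, pred$prob, windows,
                            prob_threshold = cfg$prob_threshold,
                            min_windows = cfg$min_bout_windows,
                            clipped = clipped, window_s = cfg$window_s)
  audit$status[clipped] <- "dropped:clipped"

  bout_data <- list()
  stride_rows <- list()
  prev_frame <- list(right = NULL, left = NULL)
  for (bi in seq_along(bw$bouts)) {
    bout <- bw$bouts[[bi]]
    idx <- bout$window_indices
    pb <- process_bout(rec, cc, bout$start, bout$end, cfg, prev_frame)
    prev_frame <- pb$prev_frame
    if (nrow(pb$strides)) {
      stride_rows[[length(stride_rows) + 1]] <- cbind(bout_id = bi, pb$strides)
    }
    if (!is.null(pb$drop_reason)) {
      audit$status[idx] <- pb$drop_reason
      next
    }
    audit$status[idx] <- "analyzed"
    bout_data[[length(bout_data) + 1]] <-
      list(bout_id = bi, start = bout$start, per_leg = pb$per_leg)
  }

  # per-leg per-day sEMG normalization over all retained strides
  records_raw <- data.frame()
  if (length(bout_data)) {
    legs <- c(right = "right", left = "left")
    norm <- lapply(legs, function(leg) {
      v <- unlist(lapply(bout_data, function(bd)
        lapply(bd$per_leg[[leg]], `[[`, "emg")))
      q <- stats::quantile(v, cfg$emg_norm_quantile, names = FALSE)
      if (q <= 0) 1 else q
    })
    injured <- cfg$injured_leg
    healthy <- setdiff(c("right", "left"), injured)
    recs <- lapply(bout_data, function(bd) {
      normalize_leg <- function(leg) {
        lapply(bd$per_leg[[leg]], function(s) {
          s$emg <- s$emg / norm[[leg]]
          s
        })
      }
      r <- tryCatch(
        bout_asymmetry(normalize_leg(injured), normalize_leg(healthy),
                       bout_id = bd$bout_id, subject_id = rec$subject_id,
                       timestamp = bd$start),
        error = function(e) NULL
      )
      r
    })
    ok <- !vapply(recs, is.null, logical(1))
    for (bd in bout_data[!ok]) {
      audit$status[bw$bouts[[bd$bout_id]]$window_indices] <- "dropped:undefined_asymmetry"
    }
    if (any(ok)) {
      records_raw <- do.call(rbind, lapply(recs[ok], function(r) {
        as.data.frame(r[c("bout_id", "subject_id", "timestamp",
                          asymmetry_index_names(), "composite",
                          "n_strides_i", "n_strides_h")])
      }))
    }
  }
  records <- if (nrow(records_raw)) remove_outlier_asymmetries(records_raw) else records_raw
  if (nrow(records_raw) > nrow(records)) {
    dropped_bouts <- setdiff(records_raw$bout_id, records$bout_id)
    for (b in dropped_bouts) {
      audit$status[bw$bouts[[b]]$window_indices] <- "dropped:outlier_record"
    }
  }
  strides_df <- if (length(stride_rows)) do.call(rbind, stride_rows) else data.frame()
  summary <- day_summary(bw, records, strides_df, cfg, rec)
  list(summary = summary, records = records, records_raw = records_raw,
       strides = strides_df, audit = audit, bouts = bw$bouts)
}

day_summary <- function(bw, records, strides_df, cfg, rec = NULL) {
  retained <- if (nrow(strides_df)) strides_df[strides_df$retained, , drop = FALSE] else strides_df
  idx_means <- if (nrow(records)) {
    colMeans(records[, c(asymmetry_index_names(), "composite"), drop = FALSE])
  } else {
    stats::setNames(rep(NA_real_, 8), c(asymmetry_index_names(), "composite"))
  }
  out <- list(
    subject_id = if (!is.null(rec)) rec$subject_id else NA_character_,
    total_walking_time_h = (if (is.list(bw) && !is.null(bw$walking_time_s)) bw$walking_time_s else 0) / 3600,
    n_strides = nrow(retained),
    mean_stride_time = if (nrow(retained)) mean(retained$stride_time) else NA_real_,
    index_means = idx_means,
    n_bouts_analyzed = if (nrow(records)) nrow(records) else 0L
  )
  if (isTRUE(cfg$bin_enabled) && nrow(records)) {
    bin <- floor(records$timestamp / (cfg$bin_minutes * 60))
    out$bins <- do.call(rbind, lapply(split(records, bin), function(d) {
      data.frame(bin_start_s = min(floor(d$timestamp / (cfg$bin_minutes * 60))) *
                   cfg$bin_minutes * 60,
                 composite_mean = mean(d$composite), n_bouts = nrow(d))
    }))
    rownames(out$bins) <- NULL
  }
  structure(out, class = "subject_day_summary")
}

#' @export
print.subject_day_summary <- function(x, ...) {
  cat(sprintf("<subject_day_summary> %s\n", x$subject_id))
  cat(sprintf("  walking time: %.2f h, strides: %d, mean ST: %.3f s\n",
              x$total_walking_time_h, x$n_strides,
              if (is.na(x$mean_stride_time)) NA else x$mean_stride_time))
  if (!all(is.na(x$index_means))) {
    cat("  daily index means:\n")
    print(round(x$index_means, 4))
  }
  invisible(x)
}

#' Cohen's d effect size
#'
#' Absolute standardized mean difference with pooled SD.
#'
#' @param x,y Numeric samples.
#' @return Non-negative scalar.
#' @export
cohen_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  abs(mean(x) - mean(y)) / sp
}

effect_band <- function(d) {
  if (d < 0.25) "weak" else if (d < 0.5) "small" else if (d < 1.0) "medium" else "large"
}

#' Compare daily gait summaries between groups
#'
#' Kolmogorov-Smirnov normality check per group, then one-way ANOVA (or
#' Kruskal-Wallis if normality is rejected), Tukey post-hoc contrasts
#' when significant, pairwise Cohen's d with qualitative bands, and
#' optional Spearman correlation with recovery time.
#'
#' @param values Numeric per-subject daily values (e.g. composite means).
#' @param groups Group labels aligned to `values`.
#' @param recovery_time Optional numeric recovery times for the Spearman
#'   association (pairs with non-`NA` entries used).
#' @param alpha Significance level (default 0.05).
#' @return List: `normality` (per-group KS p), `test`, `p`, `posthoc`,
#'   `effect_sizes` (pairwise d and band), `excluded` (groups with n < 2),
#'   `spearman` (rho, p) when `recovery_time` given.
#' @export
summarize_groups <- function(values, groups, recovery_time = NULL, alpha = 0.05) {
  groups <- as.factor(as.character(groups))
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2]
  keep <- !(groups %in% excluded)
  v <- values[keep]
  g <- droplevels(groups[keep])
  if (nlevels(g) < 2) stop("need at least two groups with n >= 2", call. = FALSE)
  ks_p <- vapply(split(v, g), function(x) {
    if (stats::sd(x) == 0) return(1)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }, numeric(1))
  normal <- all(ks_p > alpha)
  if (normal) {
    fit <- stats::aov(v ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    test <- "anova"
    posthoc <- if (!is.na(p) && p <= alpha) stats::TukeyHSD(fit)$g else NULL
  } else {
    p <- stats::kruskal.test(v, g)$p.value
    test <- "kruskal"
    posthoc <- NULL
  }
  pairs <- utils::combn(levels(g), 2)
  effect_sizes <- do.call(rbind, apply(pairs, 2, function(pr) {
    d <- cohen_d(v[g == pr[1]], v[g == pr[2]])
    data.frame(group1 = pr[1], group2 = pr[2], d = d, band = effect_band(d))
  }))
  out <- list(normality = ks_p, test = test, p = p, posthoc = posthoc,
              effect_sizes = effect_sizes, excluded = excluded)
  if (!is.null(recovery_time)) {
    ok <- keep & !is.na(recovery_time)
    ct <- suppressWarnings(
      stats::cor.test(values[ok], recovery_time[ok], method = "spearman"))
    out$spearman <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  out
}
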