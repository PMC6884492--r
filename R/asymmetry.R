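# Inter-limb asymmetry analysis.
#
# Per walking bout, seven indices compare the injured and healthy leg:
# three discrete relative differences |I - H| / |H| (duty factor, mean
# normalized sEMG during stance, mean normalized sEMG during swing) and
# four waveform pattern asymmetries (1 - r) / 2 where r is the Pearson
# correlation of the ensemble-mean gait-cycle waveforms (sEMG envelope,
# CC, AP, ML). The composite score is the mean of the seven.

#' Linear envelope of a surface EMG signal
#'
#' Band-pass (cascade of 4th-order Butterworth highpass and lowpass),
#' full-wave rectification, then 6 Hz lowpass, all zero phase.
#'
#' @param semg Numeric sEMG signal (mV).
#' @param rate Sampling rate in Hz (>= 100).
#' @param band Pass band in Hz (default `c(20, 100)`); the upper edge is
#'   clipped below Nyquist.
#' @param envelope_hz Envelope lowpass cutoff (default 6 Hz).
#' @return Non-negative envelope, same length as input.
#' @export
emg_envelope <- function(semg, rate, band = c(20, 100), envelope_hz = 6) {
  if (rate < 100) stop("sEMG rate must be at least 100 Hz", call. = FALSE)
  if (length(semg) < 8 * max(4, round(rate / band[1]))) {
    stop("envelope error: segment shorter than filter warm-up", call. = FALSE)
  }
  hi <- min(band[2], 0.95 * rate / 2)
  x <- filtfilt_zero_phase(butter_design(4, band[1], rate, "high"), semg)
  x <- filtfilt_zero_phase(butter_design(4, hi, rate, "low"), x)
  env <- filtfilt_zero_phase(butter_design(4, envelope_hz, rate, "low"), abs(x))
  pmax(env, 0)
}

#' Time-normalize stride channels to the gait cycle
#'
#' Accelerometer channels are lowpass filtered at `kin_lowpass_hz` over
#' the whole bout before this call; here each channel is linearly
#' interpolated onto 101 equispaced points spanning foot contact (0%) to
#' the next ipsilateral foot contact (100%).
#'
#' @param channels Named list of lists `list(t = times, x = values)`
#'   covering `[t_contact, t_next_contact]`.
#' @param t_contact,t_next_contact Stride boundary times (s).
#' @param n_points Grid size (default 101).
#' @return Named list of length-`n_points` numeric vectors.
#' @export
normalize_stride_waveforms <- function(channels, t_contact, t_next_contact,
                                       n_points = 101) {
  grid <- seq(t_contact, t_next_contact, length.out = n_points)
  lapply(channels, function(ch) {
    stats::approx(ch$t, ch$x, xout = grid, rule = 2)$y
  })
}

#' Discrete asymmetry index
#'
#' Relative difference `|I - H| / |H|` between a discrete variable of the
#' injured (`I`) and healthy (`H`) leg; 0.5 means the between-leg
#' difference is 50% of the healthy leg's value.
#'
#' @param injured,healthy Scalar values of the variable for each leg.
#' @return Non-negative scalar.
#' @export
discrete_asymmetry <- function(injured, healthy) {
  if (!is.finite(injured) || !is.finite(healthy)) {
    stop("undefined asymmetry: non-finite input", call. = FALSE)
  }
  if (healthy == 0) stop("undefined asymmetry: healthy-leg value is zero", call. = FALSE)
  abs(injured - healthy) / abs(healthy)
}

#' Waveform pattern asymmetry
#'
#' `(1 - r) / 2` where `r` is the Pearson correlation of the two
#' ensemble-mean gait-cycle waveforms; 0 for identical patterns, 1 for
#' perfectly anti-phase patterns.
#'
#' @param injured_mean,healthy_mean Equal-length numeric waveforms
#'   (101-point gait-cycle grids) with nonzero variance.
#' @return Scalar in `[0, 1]`.
#' @export
waveform_asymmetry <- function(injured_mean, healthy_mean) {
  stopifnot(length(injured_mean) == length(healthy_mean))
  if (stats::sd(injured_mean) == 0 || stats::sd(healthy_mean) == 0) {
    stop("undefined asymmetry: zero-variance waveform", call. = FALSE)
  }
  (1 - stats::cor(injured_mean, healthy_mean)) / 2
}

#' Per-bout asymmetry record
#'
#' @param stride_waveforms_i,stride_waveforms_h Lists (one element per
#'   retained stride of the injured / healthy leg). Each element is a
#'   list with the 101-point channels `emg`, `CC`, `AP`, `ML` and the
#'   stride's `duty_factor`. The sEMG channel must already be normalized
#'   (per leg, per day) by its 95th-percentile envelope value.
#' @param bout_id,subject_id,timestamp Identifiers carried through.
#' @return An `asymmetry_record`: three discrete indices (`a_df`,
#'   `a_emg_stance`, `a_emg_swing`), four waveform indices (`a_emg_t`,
#'   `a_cc_t`, `a_ap_t`, `a_ml_t`), and `composite` = mean of the seven.
#' @export
bout_asymmetry <- function(stride_waveforms_i, stride_waveforms_h,
                           bout_id = 1L, subject_id = "S01", timestamp = NA) {
  if (length(stride_waveforms_i) < 2 || length(stride_waveforms_h) < 2) {
    stop("need at least two retained strides per leg", call. = FALSE)
  }
  leg_stats <- function(sw) {
    dfm <- mean(vapply(sw, `[[`, numeric(1), "duty_factor"))
    stance_means <- vapply(sw, function(s) {
      boundary <- round(s$duty_factor * 100)
      mean(s$emg[seq_len(boundary + 1)])
    }, numeric(1))
    swing_means <- vapply(sw, function(s) {
      boundary <- round(s$duty_factor * 100)
      mean(s$emg[(boundary + 2):101])
    }, numeric(1))
    ens <- lapply(c(emg = "emg", CC = "CC", AP = "AP", ML = "ML"), function(ch) {
      rowMeans(vapply(sw, `[[`, numeric(101), ch))
    })
    list(df = dfm, emg_stance = mean(stance_means),
         emg_swing = mean(swing_means), ens = ens)
  }
  li <- leg_stats(stride_waveforms_i)
  lh <- leg_stats(stride_waveforms_h)
  rec <- list(
    a_df = discrete_asymmetry(li$df, lh$df),
    a_emg_stance = discrete_asymmetry(li$emg_stance, lh$emg_stance),
    a_emg_swing = discrete_asymmetry(li$emg_swing, lh$emg_swing),
    a_emg_t = waveform_asymmetry(li$ens$emg, lh$ens$emg),
    a_cc_t = waveform_asymmetry(li$ens$CC, lh$ens$CC),
    a_ap_t = waveform_asymmetry(li$ens$AP, lh$ens$AP),
    a_ml_t = waveform_asymmetry(li$ens$ML, lh$ens$ML)
  )
  rec$composite <- mean(unlist(rec[asymmetry_index_names()]))
  rec$n_strides_i <- length(stride_waveforms_i)
  rec$n_strides_h <- length(stride_waveforms_h)
  rec$bout_id <- bout_id
  rec$subject_id <- subject_id
  rec$timestamp <- timestamp
  structure(rec, class = "asymmetry_record")
}

#' Names of the seven asymmetry indices
#' @return Character vector of length 7.
#' @export
asymmetry_index_names <- function() {
  c("a_df", "a_emg_stance", "a_emg_swing",
    "a_emg_t", "a_cc_t", "a_ap_t", "a_ml_t")
}

#' Remove outlier asymmetry records per subject
#'
#' Records whose composite score falls outside
#' `median +/- 1.5 * IQR` of the subject's composites are dropped whole;
#' subjects with fewer than `min_n` records pass through untouched.
#'
#' @param records Data frame of asymmetry records (needs `subject_id`
#'   and `composite` columns).
#' @param min_n Minimum records per subject before filtering applies
#'   (default 4).
#' @return Filtered data frame, attribute `n_removed`.
#' @export
remove_outlier_asymmetries <- function(records, min_n = 4) {
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$subject_id), function(idx) {
    x <- records$composite[idx]
    if (length(idx) < min_n) return(idx)
    md <- stats::median(x)
    iqr <- stats::IQR(x)
    idx[x >= md - 1.5 * iqr & x <= md + 1.5 * iqr]
  }))
  keep <- sort(keep)
  structure(records[keep, , drop = FALSE],
            n_removed = nrow(records) - length(keep))
}

#' @export
print.asymmetry_record <- function(x, ...) {
  cat(sprintf("<asymmetry_record> bout %s subject %s\n", x$bout_id, x$subject_id))
  v <- unlist(x[c(asymmetry_index_names(), "composite")])
  print(round(v, 4))
  invisible(x)
}
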