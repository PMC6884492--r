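# Stride extraction and gait phase segmentation from the cranial-caudal
# acceleration of one thigh.
#
# Cadence first: the dominant Welch-PSD peak in the physiologic stride
# band gives f_stride, and the dominant peak near its second harmonic
# gives f_step. The signal is then lowpass filtered three ways (5 Hz,
# f_step, f_stride cutoffs, zero phase). Local minima of the
# f_stride-filtered trace, confirmed by a nearby minimum of the
# f_step-filtered trace, mark foot off; the first upward 1 g crossing of
# the 5 Hz-filtered trace after each foot off marks foot contact.

#' Estimate stride and step frequency from CC acceleration
#'
#' @param cc Numeric CC acceleration (g), at least 8 s.
#' @param rate Sampling rate (Hz).
#' @param stride_band Physiologic stride-frequency band in Hz
#'   (default `c(0.5, 1.4)`).
#' @param step_rel Step-frequency search band relative to `f_stride`
#'   (default `c(1.5, 2.5)`).
#' @param min_peak_ratio Dominance requirement: peak power must exceed
#'   this multiple of the median in-band power (default 3); otherwise a
#'   cadence error is raised and the bout is skipped.
#' @return List with `f_stride` and `f_step` (Hz).
#' @export
estimate_cadence <- function(cc, rate, stride_band = c(0.5, 1.4),
                             step_rel = c(1.5, 2.5), min_peak_ratio = 3) {
  if (length(cc) < 8 * rate) stop("cadence error: segment shorter than 8 s", call. = FALSE)
  w <- welch_psd(cc, rate)
  pick <- function(band) {
    in_band <- which(w$freq >= band[1] & w$freq <= band[2])
    if (length(in_band) < 3) stop("cadence error: empty search band", call. = FALSE)
    p <- w$power[in_band]
    # interior local maxima of the in-band spectrum
    loc <- in_band[which(diff(sign(diff(p))) == -2) + 1]
    if (!length(loc)) stop("cadence error: no spectral peak in band", call. = FALSE)
    i <- loc[which.max(w$power[loc])]
    # dominance vs the in-band noise floor, leakage around the peak excluded
    floor_bins <- in_band[abs(w$freq[in_band] - w$freq[i]) > 0.3]
    if (length(floor_bins) >= 3 &&
        w$power[i] < min_peak_ratio * stats::median(w$power[floor_bins])) {
      stop("cadence error: no dominant spectral peak", call. = FALSE)
    }
    refine_peak(w$freq, w$power, i)
  }
  f_stride <- pick(stride_band)
  f_step <- pick(f_stride * step_rel)
  list(f_stride = f_stride, f_step = f_step)
}

local_minima <- function(x) which(diff(sign(diff(x))) == 2) + 1

#' Detect foot-off and foot-contact events
#'
#' @param cc Numeric CC acceleration (g) of one walking bout, one leg.
#' @param rate Sampling rate (Hz).
#' @param cadence List with `f_stride`, `f_step` from [estimate_cadence()].
#' @param t0 Time of the first sample (s), for absolute event times.
#' @param event_filter_hz Cutoff of the contact-detection lowpass
#'   (default 5 Hz).
#' @param order Butterworth order for every bank member (default 4).
#' @param min_depth Minimum swing-trough depth below the signal mean for a
#'   foot-off candidate, in g (default 0.05); rejects flat signals.
#' @return A `gait_events` list with sorted, alternating `foot_offs` and
#'   `foot_contacts` (s); contacts are interpolated between samples at
#'   the 1 g crossing.
#' @export
detect_gait_events <- function(cc, rate, cadence, t0 = 0,
                               event_filter_hz = 5, order = 4,
                               min_depth = 0.05) {
  lp5 <- filtfilt_zero_phase(butter_design(order, event_filter_hz, rate), cc)
  lp_step <- filtfilt_zero_phase(butter_design(order, cadence$f_step, rate), cc)
  lp_stride <- filtfilt_zero_phase(butter_design(order, cadence$f_stride, rate), cc)
  cand <- local_minima(lp_stride)
  cand <- cand[lp_stride[cand] < mean(lp_stride) - min_depth]
  step_min <- local_minima(lp_step)
  win <- 0.25 / cadence$f_step * rate  # confirmation window in samples
  confirmed <- cand[vapply(cand, function(i) any(abs(step_min - i) <= win), logical(1))]
  offs <- t0 + (confirmed - 1) / rate
  contacts <- numeric(0)
  off_kept <- numeric(0)
  n <- length(cc)
  for (k in seq_along(confirmed)) {
    i_from <- confirmed[k]
    i_to <- if (k < length(confirmed)) confirmed[k + 1] else n
    if (i_to <= i_from + 1) next
    seg <- i_from:(i_to - 1)
    up <- seg[which(lp5[seg] < 1 & lp5[seg + 1] >= 1)]
    if (!length(up)) next  # no stance onset before next foot off: cycle dropped
    i <- up[1]
    frac <- (1 - lp5[i]) / (lp5[i + 1] - lp5[i])
    contacts <- c(contacts, t0 + (i - 1 + frac) / rate)
    off_kept <- c(off_kept, offs[k])
  }
  structure(list(foot_offs = off_kept, foot_contacts = contacts),
            class = "gait_events")
}

#' Segment strides from gait events
#'
#' Consecutive same-leg foot contacts delimit strides; the foot off in
#' between defines stance. Strides outside the stride-time or duty-factor
#' constraints are rejected with a reason.
#'
#' @param events A `gait_events` list (one leg).
#' @param st_bounds Admissible stride time in s (default `c(0.91, 1.57)`).
#' @param df_bounds Admissible duty factor (default `c(0.44, 0.73)`).
#' @return List with `strides` (data frame: `t_contact`, `t_off`,
#'   `t_next_contact`, `stride_time`, `duty_factor`, `retained`,
#'   `reason`) and `retained` (the retained subset).
#' @export
segment_strides <- function(events, st_bounds = c(0.91, 1.57),
                            df_bounds = c(0.44, 0.73)) {
  fc <- sort(events$foot_contacts)
  fo <- sort(events$foot_offs)
  rows <- list()
  if (length(fc) >= 2) {
    for (k in seq_len(length(fc) - 1)) {
      c0 <- fc[k]
      c1 <- fc[k + 1]
      off <- fo[fo > c0 & fo < c1]
      if (!length(off)) {
        rows[[length(rows) + 1]] <- data.frame(
          t_contact = c0, t_off = NA_real_, t_next_contact = c1,
          stride_time = c1 - c0, duty_factor = NA_real_,
          retained = FALSE, reason = "no_foot_off")
        next
      }
      st <- c1 - c0
      df <- (off[1] - c0) / st
      reason <- ""
      if (st < st_bounds[1] || st > st_bounds[2]) {
        reason <- "stride_time_out_of_bounds"
      } else if (df < df_bounds[1] || df > df_bounds[2]) {
        reason <- "duty_factor_out_of_bounds"
      }
      rows[[length(rows) + 1]] <- data.frame(
        t_contact = c0, t_off = off[1], t_next_contact = c1,
        stride_time = st, duty_factor = df,
        retained = reason == "", reason = reason)
    }
  }
  strides <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_contact = numeric(0), t_off = numeric(0),
               t_next_contact = numeric(0), stride_time = numeric(0),
               duty_factor = numeric(0), retained = logical(0),
               reason = character(0))
  list(strides = strides, retained = strides[strides$retained, , drop = FALSE])
}
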