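# Window feature extraction for the walking classifier.
#
# Six canonical features survived Davies-Bouldin selection on the original
# training corpus and are always computed; the registry is extensible so a
# larger bank can be screened the same way.

.feature_registry <- new.env(parent = emptyenv())

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    structure(0, flagged = TRUE)
  } else {
    stats::cor(x, y)
  }
}

# fraction of total (DC-inclusive) periodogram power below f_lim
low_freq_power_fraction <- function(x, rate, f_lim = 0.25) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  nfreq <- floor(n / 2) + 1
  p <- sp[seq_len(nfreq)]
  f <- (seq_len(nfreq) - 1) * rate / n
  tot <- sum(p)
  if (tot == 0) return(1)
  sum(p[f < f_lim]) / tot
}

#' Register a window feature
#'
#' @param name Feature name.
#' @param fn Function `(channels, rate)` where `channels` is a list of
#'   equal-length numeric vectors `CC_R`, `CC_L`, `AP_R`, `AP_L`, `ML_R`,
#'   `ML_L`, returning a single finite numeric.
#' @export
register_feature <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .feature_registry)
  invisible(name)
}

#' List registered feature names
#' @return Character vector (canonical six first, in canonical order).
#' @export
feature_registry <- function() {
  nm <- ls(.feature_registry)
  canon <- canonical_features()
  c(canon, setdiff(nm, canon))
}

#' Names of the six canonical walking features
#' @return Character vector of length 6.
#' @export
canonical_features <- function() {
  c("cc_q25_mean", "cc_ap_crosscorr", "cc_bilateral_corr",
    "ap_skewness_mean", "ap_lowfreq_power", "ap_median_mean")
}

local({
  reg <- function(name, fn) assign(name, fn, envir = .feature_registry)
  # (i) mean of the 25th quantiles of CC_R and CC_L
  reg("cc_q25_mean", function(ch, rate) {
    mean(c(stats::quantile(ch$CC_R, 0.25, names = FALSE),
           stats::quantile(ch$CC_L, 0.25, names = FALSE)))
  })
  # (ii) mean correlation of CC_R~AP_L and CC_L~AP_R
  reg("cc_ap_crosscorr", function(ch, rate) {
    mean(c(safe_cor(ch$CC_R, ch$AP_L), safe_cor(ch$CC_L, ch$AP_R)))
  })
  # (iii) correlation of CC_R with CC_L
  reg("cc_bilateral_corr", function(ch, rate) safe_cor(ch$CC_R, ch$CC_L))
  # (iv) mean skewness of AP_R and AP_L
  reg("ap_skewness_mean", function(ch, rate) {
    mean(c(sample_skewness(ch$AP_R), sample_skewness(ch$AP_L)))
  })
  # (v) mean fraction of signal power below 0.25 Hz in AP_R and AP_L
  reg("ap_lowfreq_power", function(ch, rate) {
    mean(c(low_freq_power_fraction(ch$AP_R, rate),
           low_freq_power_fraction(ch$AP_L, rate)))
  })
  # (vi) mean of the medians of AP_R and AP_L
  reg("ap_median_mean", function(ch, rate) {
    mean(c(stats::median(ch$AP_R), stats::median(ch$AP_L)))
  })
})

#' Extract features from one analysis window
#'
#' @param channels List of anatomical channels `CC_R`, `CC_L`, `AP_R`,
#'   `AP_L` (and optionally `ML_R`, `ML_L`), equal-length numeric vectors.
#' @param rate Accelerometer sampling rate in Hz.
#' @param features Feature names to compute (default: all registered).
#' @return Named numeric vector; zero-variance correlations are returned
#'   as 0 with attribute `flagged_features` listing the affected names.
#' @export
extract_features <- function(channels, rate, features = feature_registry()) {
  stopifnot(all(c("CC_R", "CC_L", "AP_R", "AP_L") %in% names(channels)))
  flagged <- character(0)
  vals <- vapply(features, function(nm) {
    fn <- get(nm, envir = .feature_registry)
    v <- fn(channels, rate)
    if (isTRUE(attr(v, "flagged"))) flagged <<- c(flagged, nm)
    as.numeric(v)
  }, numeric(1))
  if (any(!is.finite(vals))) {
    stop("non-finite feature value(s): ",
         paste(features[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  structure(vals, flagged_features = flagged)
}

#' Extract the feature matrix for a set of windows
#'
#' Runs per-window anatomical calibration (AP/ML via transverse-plane PCA
#' with sign continuity) and feature extraction for both legs.
#'
#' @param windows List of windows from [partition_windows()].
#' @param cc_r,cc_l Per-leg CC axes from [estimate_cc_axis()].
#' @param rate Accelerometer rate (Hz).
#' @param features Feature names (default registry).
#' @return Data frame, one row per window, with `window_index` plus one
#'   column per feature.
#' @export
window_feature_matrix <- function(windows, cc_r, cc_l, rate,
                                  features = feature_registry()) {
  prev_r <- NULL
  prev_l <- NULL
  rows <- lapply(windows, function(w) {
    fr <- estimate_ap_ml_axes(w$accel_R, cc_r, prev = prev_r)
    fl <- estimate_ap_ml_axes(w$accel_L, cc_l, prev = prev_l)
    prev_r <<- fr
    prev_l <<- fl
    ar <- to_anatomical(w$accel_R, fr)
    al <- to_anatomical(w$accel_L, fl)
    ch <- list(CC_R = ar[, "CC"], AP_R = ar[, "AP"], ML_R = ar[, "ML"],
               CC_L = al[, "CC"], AP_L = al[, "AP"], ML_L = al[, "ML"])
    c(window_index = w$index, extract_features(ch, rate, features))
  })
  as.data.frame(do.call(rbind, rows))
}
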