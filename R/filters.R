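# Minimal IIR filter design and spectral estimation.
#
# The pre-installed stack ships no DSP package, and the event detector is
# defined directly in terms of a Butterworth lowpass filter bank and a Welch
# PSD, so these primitives are implemented here. Designs follow the standard
# bilinear-transform route and are unit-tested against coefficients frozen
# from an independent reference implementation.

# Polynomial coefficients (descending powers) from roots, complex-safe.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

#' Design a digital Butterworth filter
#'
#' Bilinear-transform design of a lowpass or highpass Butterworth filter.
#'
#' @param order Filter order (positive integer).
#' @param fc Cutoff frequency in Hz (-3 dB point).
#' @param fs Sampling frequency in Hz; `fc` must lie in `(0, fs/2)`.
#' @param type `"low"` or `"high"`.
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (descending powers of `z^-1`, `a[1] == 1`).
#' @export
butter_design <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  k <- seq_len(order)
  # analog prototype poles, unit cutoff, left half plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * fc / fs)  # pre-warped analog cutoff
  if (type == "low") {
    pa <- wc * p
    zd <- rep(-1 + 0i, order)
  } else {
    pa <- wc / p
    zd <- rep(1 + 0i, order)
  }
  pd <- (2 * fs + pa) / (2 * fs - pa)
  gain <- if (type == "low") {
    Re(wc^order / prod(2 * fs - pa))
  } else {
    Re((2 * fs)^order / prod(2 * fs - pa))
  }
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# One-pass IIR filter (zero initial conditions) via the convolution +
# recursive decomposition of a*y = b*x; both passes run in compiled code.
iir_filter <- function(coef, x) {
  b <- coef$b
  a <- coef$a
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase filtering
#'
#' Applies an IIR filter forward and backward with odd (antisymmetric)
#' edge extension so the net response has zero phase, as required for
#' event timing to be unbiased.
#'
#' @param coef Filter as returned by [butter_design()].
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(coef, x) {
  n <- length(x)
  ntaps <- max(length(coef$a), length(coef$b))
  pad <- min(n - 1, 3 * ntaps)
  if (pad < 1) stop("signal too short for zero-phase filtering", call. = FALSE)
  head_ext <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(coef, xe)
  y <- rev(iir_filter(coef, rev(y)))
  y[seq(pad + 1, pad + n)]
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann window, 50% overlap and
#' per-segment mean removal (optional). One-sided density scaling.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param nperseg Segment length in samples (default `min(4 s * fs, N/2)`,
#'   at least 16).
#' @param nfft FFT length; defaults to 8x zero padding of the next power of
#'   two above `nperseg`, which sharpens peak interpolation.
#' @param demean Remove each segment's mean before windowing (default TRUE).
#' @return A list with `freq` (Hz) and `power` (signal units^2 / Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL, nfft = NULL, demean = TRUE) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- max(16L, min(round(4 * fs), floor(n / 2)))
  nperseg <- min(nperseg, n)
  if (is.null(nfft)) nfft <- 8L * 2L^ceiling(log2(nperseg))
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / nperseg))
  u <- sum(w^2)
  nfreq <- nfft %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    seg <- seg * w
    sp <- stats::fft(c(seg, rep(0, nfft - nperseg)))[seq_len(nfreq)]
    acc <- acc + Mod(sp)^2
  }
  p <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nfreq] <- 1
  list(freq = seq(0, nfreq - 1L) * fs / nfft, power = p * dbl)
}

# Parabolic refinement of a spectral peak on log power; returns frequency.
refine_peak <- function(freq, power, i) {
  if (i <= 1 || i >= length(power)) return(freq[i])
  lp <- log(pmax(power[(i - 1):(i + 1)], .Machine$double.xmin))
  den <- lp[1] - 2 * lp[2] + lp[3]
  if (den >= 0) return(freq[i])
  delta <- 0.5 * (lp[1] - lp[3]) / den
  freq[i] + delta * (freq[2] - freq[1])
}
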