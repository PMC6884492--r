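# Sensor-to-thigh anatomical calibration.
#
# The sensor sits on the rectus femoris with arbitrary (but constant)
# orientation. A quiet standing trial gives the cranial-caudal (CC) axis as
# the gravity direction (thigh assumed upright, CC directed proximally =
# anti-gravity). Within each 4-s window, the first principal component of
# acceleration in the transverse plane gives the antero-posterior (AP)
# axis; medio-lateral (ML) completes the right-handed triad ML = CC x AP.

unit <- function(v) v / sqrt(sum(v^2))

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Estimate the cranial-caudal axis from a standing trial
#'
#' The mean acceleration during quiet upright standing measures gravity in
#' the sensor frame; the CC axis (proximal) is taken along it. The mean
#' vector must have near-1 g magnitude and the subject must be still.
#'
#' @param standing_accel 3-column matrix of accelerations (g) covering at
#'   least 2 s of quiet standing.
#' @param max_sd Per-axis standard deviation allowed before the trial is
#'   rejected as motion-contaminated (default 0.05 g).
#' @param norm_bounds Acceptable mean-vector magnitude in g
#'   (default `c(0.8, 1.2)`).
#' @return Unit 3-vector (CC axis, sensor frame).
#' @export
estimate_cc_axis <- function(standing_accel, max_sd = 0.05,
                             norm_bounds = c(0.8, 1.2)) {
  m <- as.matrix(standing_accel)
  stopifnot(ncol(m) == 3)
  sds <- apply(m, 2, stats::sd)
  if (any(sds > max_sd)) {
    stop("calibration error: subject moving during standing trial", call. = FALSE)
  }
  g <- colMeans(m)
  gn <- sqrt(sum(g^2))
  if (gn < norm_bounds[1] || gn > norm_bounds[2]) {
    stop("calibration error: mean acceleration magnitude outside [0.8, 1.2] g",
         call. = FALSE)
  }
  # for an upright thigh the accelerometer reads +1 g along the proximal
  # direction (reaction to gravity), so CC is along the mean itself
  unit(g)
}

#' Estimate AP and ML axes for one analysis window
#'
#' Projects the window's acceleration onto the plane orthogonal to CC and
#' takes the first principal component as the AP axis. PCA is
#' sign-ambiguous; the sign making the AP channel's skewness non-negative
#' is chosen, and when the skewness is too small to be reliable
#' (`|skew| < 0.1`) the previous window's sign convention is inherited.
#'
#' @param window_accel 3-column matrix of accelerations (g), one window.
#' @param cc Unit CC axis from [estimate_cc_axis()].
#' @param prev Optional previous window's frame (list with `ap`), used for
#'   sign continuity and as fallback for degenerate windows.
#' @param min_var Transverse variance (g^2) below which the window is
#'   flagged axis-indeterminate (default 1e-6).
#' @return A list `anatomical_frame` with unit vectors `cc`, `ap`, `ml`,
#'   and `indeterminate` flag.
#' @export
estimate_ap_ml_axes <- function(window_accel, cc, prev = NULL, min_var = 1e-6) {
  m <- as.matrix(window_accel)
  stopifnot(ncol(m) == 3)
  cc <- unit(cc)
  proj <- m - outer(drop(m %*% cc), cc)  # remove CC component
  cv <- stats::cov(proj)
  tot_var <- sum(diag(cv))
  if (!is.finite(tot_var) || tot_var < min_var) {
    ap_fallback <- if (!is.null(prev)) {
      prev$ap
    } else {
      # deterministic transverse axis: component of the sensor axis least
      # aligned with CC, projected into the transverse plane
      e <- diag(3)[, which.min(abs(cc))]
      unit(e - sum(e * cc) * cc)
    }
    return(structure(list(cc = cc, ap = ap_fallback,
                          ml = unit(cross3(cc, ap_fallback)),
                          indeterminate = TRUE),
                     class = "anatomical_frame"))
  }
  e <- eigen(cv, symmetric = TRUE)
  ap <- e$vectors[, 1]
  ap <- unit(ap - sum(ap * cc) * cc)  # numerical re-orthogonalization
  sk <- sample_skewness(drop(proj %*% ap))
  if (abs(sk) >= 0.1) {
    if (sk < 0) ap <- -ap
  } else if (!is.null(prev) && sum(ap * prev$ap) < 0) {
    ap <- -ap
  }
  ml <- unit(cross3(cc, ap))
  structure(list(cc = cc, ap = ap, ml = ml, indeterminate = FALSE),
            class = "anatomical_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project raw acceleration onto anatomical axes
#'
#' @param accel 3-column matrix of raw sensor-frame accelerations (g).
#' @param frame An `anatomical_frame` from [estimate_ap_ml_axes()] (or a
#'   list with unit vectors `cc`, `ap`, `ml`).
#' @return Matrix with columns `CC`, `AP`, `ML`; per-sample vector norm is
#'   preserved.
#' @export
to_anatomical <- function(accel, frame) {
  m <- as.matrix(accel)
  out <- cbind(CC = drop(m %*% frame$cc),
               AP = drop(m %*% frame$ap),
               ML = drop(m %*% frame$ml))
  out
}
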