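# Synthetic bilateral gait and activity generator.
#
# Emulates the signal properties of a thigh-worn sensor per leg (tri-axial
# accel at 31.25 Hz, sEMG at 250 Hz) with full ground truth: every foot
# contact / foot off, per-stride stride time and duty factor, activity
# labels, and the injected asymmetries. No musculoskeletal forward model is
# attempted; the cycle waveform is a band-limited (4-harmonic) shape
# constructed so that the published event definitions hold exactly in the
# noise-free signal:
#   * the fundamental's minimum sits at the duty-factor phase (foot off),
#   * the first upward 1 g crossing after it sits at the stride boundary
#     (foot contact).
# The second condition is imposed by a one-dimensional root solve over a
# phase offset of the fundamental at simulation time.

#' Gait simulation configuration
#'
#' @param stride_time Stride time in s (`[0.7, 2.2]`, default 1.10).
#' @param duty_factor Healthy-leg duty factor (`(0.4, 0.8)`, the waveform
#'   family's reachable domain; default 0.60).
#' @param n_strides Strides per leg with ground truth (default 20).
#' @param asym List: `df_ratio` (injured DF = ratio x healthy DF, default
#'   1), `emg_amp_ratio` (stance-burst scaling of the injured leg, default
#'   1), `waveform_decorrelation` (target AP pattern asymmetry in
#'   `[0, 1)`, default 0).
#' @param noise_sd Accelerometer noise SD in g (default 0.03).
#' @param emg_noise_sd sEMG sensor noise SD in mV (default 0.01).
#' @param clipping Inject a clipped accelerometer run (default FALSE).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param rates List with `accel` (default 31.25) and `semg` (default 250)
#'   in Hz.
#' @param injured_leg `"right"` or `"left"` (default `"right"`).
#' @param mount_tilt_deg Sensor mounting tilt about the ML axis in degrees
#'   (default 8).
#' @param subject_id Subject label.
#' @return A validated `gait_sim_config` list.
#' @export
gait_sim_config <- function(stride_time = 1.10, duty_factor = 0.60,
                            n_strides = 20,
                            asym = list(df_ratio = 1, emg_amp_ratio = 1,
                                        waveform_decorrelation = 0),
                            noise_sd = 0.03, emg_noise_sd = 0.01,
                            clipping = FALSE, seed = 1,
                            rates = list(accel = 31.25, semg = 250),
                            injured_leg = "right", mount_tilt_deg = 8,
                            subject_id = "SIM01") {
  stopifnot(stride_time >= 0.7, stride_time <= 2.2,
            duty_factor > 0.4, duty_factor < 0.8)
  asym <- utils::modifyList(list(df_ratio = 1, emg_amp_ratio = 1,
                                 waveform_decorrelation = 0), asym)
  df_i <- duty_factor * asym$df_ratio
  if (df_i <= 0.4 || df_i >= 0.8) {
    stop("injured duty factor outside simulator bounds (0.4, 0.8)", call. = FALSE)
  }
  stopifnot(asym$waveform_decorrelation >= 0, asym$waveform_decorrelation < 1)
  structure(
    list(stride_time = stride_time, duty_factor = duty_factor,
         n_strides = as.integer(n_strides), asym = asym,
         noise_sd = noise_sd, emg_noise_sd = emg_noise_sd,
         clipping = clipping, seed = as.integer(seed), rates = rates,
         injured_leg = injured_leg, mount_tilt_deg = mount_tilt_deg,
         subject_id = subject_id),
    class = "gait_sim_config"
  )
}

# evaluate a harmonic series: coef is complex, index k = 0..K
eval_cycle <- function(coef, phase) {
  out <- rep(Re(coef[1]), length(phase))
  for (k in seq_len(length(coef) - 1)) {
    out <- out + 2 * Re(coef[k + 1] * exp(2i * pi * k * phase))
  }
  out
}

# Band-limited CC cycle deviation (g) for one duty factor; contact at
# phase 0 (upward 1 g crossing), fundamental minimum at phase = df.
#
# Construction: a continuous hump/trough shape (stance hump on [0, b],
# skewed swing trough on [b, 1]) is truncated to n_harm harmonics with
# Lanczos smoothing. For this family the event definitions give a
# "detected" duty factor equal to the phase distance from the cycle's
# upward zero crossing back to the fundamental's minimum; the breakpoint
# b is root-solved so that this equals the requested df, then the cycle
# is rotated so the contact crossing sits at phase 0.
cc_cycle_coefficients <- function(df, trough_amp = 0.40, n_harm = 4,
                                  nd = 2048) {
  # gentler trough skews give more natural shapes but cannot reach low
  # duty factors; try in order of preference
  for (skew in c(0.65, 0.40, 0.30, 0.20)) {
    co <- tryCatch(
      cc_cycle_shape(df, hump_amp = 0.20, trough_amp, skew, n_harm, nd),
      error = function(e) NULL)
    if (!is.null(co)) return(co)
  }
  stop("simulator waveform calibration failed (df=", df, ")", call. = FALSE)
}

cc_cycle_shape <- function(df, hump_amp, trough_amp, skew, n_harm, nd) {
  u <- (seq_len(nd) - 1) / nd
  sigma <- sinc_sigma(n_harm)
  coef_of <- function(b) {
    base <- ifelse(u < b,
                   hump_amp * sin(pi * u / b),
                   -trough_amp * sin(pi * ((u - b) / (1 - b))^skew))
    cf <- stats::fft(base) / nd
    c(cf[1], cf[2:(n_harm + 1)] * sigma)
  }
  # (fundamental argmin, first upward zero after it) for a coefficient set
  cycle_marks <- function(co) {
    m <- (0.5 - Arg(co[2]) / (2 * pi)) %% 1  # argmin of 2*Re(c1 e^{2pi i u})
    ph <- m + u
    v <- eval_cycle(co, ph)
    i <- which(v[-nd] < 0 & v[-1] >= 0)
    if (!length(i)) return(c(NA_real_, NA_real_))
    i <- i[1]
    frac <- -v[i] / (v[i + 1] - v[i])
    c(m, ph[i] + frac / nd)
  }
  implied_df <- function(b) {
    mk <- cycle_marks(coef_of(b))
    if (anyNA(mk)) return(NA_real_)
    mk[1] - mk[2] + 1
  }
  grid <- seq(0.08, 0.92, by = 0.04)
  gv <- vapply(grid, implied_df, numeric(1)) - df
  ok <- which(!is.na(gv))
  br <- NULL
  for (j in seq_len(length(ok) - 1)) {
    a <- ok[j]; bb <- ok[j + 1]
    if (bb == a + 1 && gv[a] * gv[bb] <= 0) { br <- c(grid[a], grid[bb]); break }
  }
  if (is.null(br)) {
    stop("simulator waveform calibration failed (df=", df, ")", call. = FALSE)
  }
  b <- stats::uniroot(function(x) implied_df(x) - df, br, tol = 1e-7)$root
  co <- coef_of(b)
  shift <- cycle_marks(co)[2] %% 1  # move the contact crossing to phase 0
  co <- co * exp(2i * pi * (0:n_harm) * shift)
  # stance excursion must clear 1 g robustly against sensor noise
  v <- eval_cycle(co, u)
  if (max(v[u < df]) < 0.06) {
    stop("stance peak too small", call. = FALSE)
  }
  co
}

# Lanczos sigma factors for harmonics 1..n (suppress Gibbs wiggles)
sinc_sigma <- function(n) {
  k <- seq_len(n)
  sin(pi * k / (n + 1)) / (pi * k / (n + 1))
}

# AP / ML base cycles (g); shared by both legs
ap_cycle <- function(phase) 0.20 * cos(2 * pi * phase - 0.3) + 0.10 * cos(4 * pi * phase + 0.8)
ml_cycle <- function(phase) 0.10 * cos(2 * pi * phase + 1.2) + 0.05 * cos(4 * pi * phase - 0.5)

# pure 3rd stride harmonic: exactly orthogonal to the two-harmonic AP base
decorr_cycle <- function(phase) cos(6 * pi * phase)

# mixing weight giving Pearson correlation r between base and
# base + lambda * z on the 101-point gait-cycle grid
solve_decorr_lambda <- function(target_a) {
  if (target_a <= 0) return(0)
  r_target <- 1 - 2 * target_a
  g <- seq(0, 1, length.out = 101)
  w <- ap_cycle(g)
  z <- decorr_cycle(g)
  f <- function(l) stats::cor(w, w + l * z) - r_target
  stats::uniroot(f, c(0, 1e3), tol = 1e-10)$root
}

# periodic gaussian bump
cycle_bump <- function(phase, center, width) {
  d <- (phase - center) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  exp(-0.5 * (d / width)^2)
}

# sEMG activation profile (mV amplitude of the modulated noise carrier)
emg_activation <- function(phase, df, stance_amp, swing_amp, baseline = 0.05) {
  baseline +
    stance_amp * cycle_bump(phase, 0.10, 0.08) +
    swing_amp * cycle_bump(phase, df + 0.12, 0.10)
}

rot_y <- function(th) {
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
}

#' Simulate a standing calibration trial
#'
#' @param tilt_deg Thigh/sensor tilt from vertical in degrees (`[0, 30]`).
#' @param seed RNG seed.
#' @param duration_s Trial length in s (default 3).
#' @param rate Sampling rate (default 31.25 Hz).
#' @param noise_sd Accelerometer noise SD in g (default 0.02).
#' @return List with `accel` (n x 3 matrix, g) and the ground-truth
#'   `cc_axis` (unit 3-vector, sensor frame).
#' @export
simulate_standing_calibration <- function(tilt_deg, seed = 1, duration_s = 3,
                                          rate = 31.25, noise_sd = 0.02) {
  stopifnot(tilt_deg >= 0, tilt_deg <= 30)
  withr::with_seed(seed, {
    n <- round(duration_s * rate)
    cc <- drop(rot_y(tilt_deg * pi / 180) %*% c(0, 0, 1))
    accel <- matrix(rep(cc, each = n), n, 3) +
      matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    list(accel = accel, cc_axis = cc)
  })
}

# band-limited EMG carrier noise, unit variance
emg_carrier <- function(n, rate) {
  x <- stats::rnorm(n)
  x <- filtfilt_zero_phase(butter_design(4, 20, rate, "high"), x)
  x <- filtfilt_zero_phase(butter_design(4, min(100, 0.95 * rate / 2), rate, "low"), x)
  x / stats::sd(x)
}

#' Simulate a bilateral walking recording with ground truth
#'
#' Both legs walk at the shared stride time, half a cycle out of phase;
#' the injured leg carries the configured duty-factor, sEMG-amplitude and
#' AP-waveform asymmetries. Two lead-in and two lead-out strides beyond
#' the `n_strides` ground-truth strides buffer filter edge effects.
#'
#' @param cfg A [gait_sim_config()].
#' @return List with `recording` ([bilateral_recording()]), `calibration`
#'   (per-leg standing trials with true CC axes), and `truth`: per-stride
#'   events and parameters (`events` data frame), per-leg duty factors,
#'   the AP decorrelation mixing weight, and the walking time span.
#' @export
simulate_gait_recording <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  withr::with_seed(cfg$seed, {
    st <- cfg$stride_time
    n_cycles <- cfg$n_strides + 4L
    duration <- (n_cycles + 1) * st
    fs_a <- cfg$rates$accel
    fs_e <- cfg$rates$semg
    legs <- c("right", "left")
    offsets <- c(right = 0.25 * st, left = 0.25 * st + st / 2)
    injured <- cfg$injured_leg
    df_by_leg <- c(right = cfg$duty_factor, left = cfg$duty_factor)
    df_by_leg[injured] <- cfg$duty_factor * cfg$asym$df_ratio
    lambda <- solve_decorr_lambda(cfg$asym$waveform_decorrelation)
    stance_amp <- c(right = 0.35, left = 0.35)
    stance_amp[injured] <- 0.35 * cfg$asym$emg_amp_ratio
    t_a <- seq(0, duration - 1 / fs_a, by = 1 / fs_a)
    t_e <- seq(0, duration - 1 / fs_e, by = 1 / fs_e)

    cc_coef <- lapply(df_by_leg, cc_cycle_coefficients)
    tilt <- cfg$mount_tilt_deg * pi / 180
    mounts <- list(right = rot_y(tilt), left = rot_y(-tilt))

    accel <- list()
    semg <- list()
    truth_rows <- list()
    calib <- list()
    for (leg in legs) {
      phase_a <- ((t_a - offsets[[leg]]) / st) %% 1
      cc <- 1 + eval_cycle(cc_coef[[leg]], phase_a)
      ap <- ap_cycle(phase_a)
      if (leg == injured && lambda > 0) ap <- ap + lambda * decorr_cycle(phase_a)
      ml <- ml_cycle(phase_a)
      anat <- rbind(ap, ml, cc)  # sensor x=AP, y=ML, z=CC before mounting
      sens <- t(mounts[[leg]] %*% anat)
      sens <- sens + matrix(stats::rnorm(length(sens), sd = cfg$noise_sd),
                            nrow(sens), 3)
      if (cfg$clipping && leg == injured) {
        sens[100:107, 3] <- 16
      }
      accel[[leg]] <- sensor_stream(sens, fs_a, leg, "accel", range_limit = 16)

      phase_e <- ((t_e - offsets[[leg]]) / st) %% 1
      act <- emg_activation(phase_e, df_by_leg[[leg]],
                            stance_amp[[leg]], swing_amp = 0.70)
      e <- act * emg_carrier(length(t_e), fs_e) +
        stats::rnorm(length(t_e), sd = cfg$emg_noise_sd)
      semg[[leg]] <- sensor_stream(matrix(e, ncol = 1), fs_e, leg, "semg")

      cal <- list(accel = matrix(rep(mounts[[leg]][, 3], each = 94), 94, 3) +
                    matrix(stats::rnorm(282, sd = 0.02), 94, 3),
                  cc_axis = mounts[[leg]][, 3])
      calib[[leg]] <- cal

      k <- 2:(2 + cfg$n_strides - 1)  # interior cycles only
      contacts <- offsets[[leg]] + k * st
      truth_rows[[leg]] <- data.frame(
        leg = leg,
        t_contact = contacts,
        t_off = contacts + df_by_leg[[leg]] * st,
        t_next_contact = contacts + st,
        stride_time = st,
        duty_factor = df_by_leg[[leg]]
      )
    }
    rec <- bilateral_recording(accel$right, accel$left, semg$right, semg$left,
                               subject_id = cfg$subject_id)
    truth <- list(
      events = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
      duty_factor = df_by_leg,
      stride_time = st,
      lambda = lambda,
      injured_leg = injured,
      walk_span = c(0, duration),
      config = cfg
    )
    list(recording = rec, calibration = calib, truth = truth)
  })
}

# ---- activity generator -----------------------------------------------

# Quasi-periodic gait-like block (stairs, crutching) in anatomical
# coordinates. Unlike level walking these gaits are irregular: the phase
# advances with smoothed random-rate jitter, decorrelating the two legs
# (stairs) unless they share the swing-through phase (crutch).
quasi_gait_block <- function(t, cycle_time, amp, jitter_sd, phase0,
                             coef_cc, rate) {
  n <- length(t)
  jit <- stats::filter(stats::rnorm(n, sd = jitter_sd), 0.98,
                       method = "recursive")
  jit <- as.numeric(jit) * sqrt(1 - 0.98^2)
  phase <- phase0 + cumsum((1 + jit) / (cycle_time * rate))
  cc <- 1 + amp * eval_cycle(coef_cc, phase)
  rbind(amp * ap_cycle(phase), amp * ml_cycle(phase), cc)
}

# static posture accel block in anatomical coordinates (AP, ML, CC rows)
static_posture_block <- function(t, posture, wobble_amp) {
  grav <- switch(posture,
    stand = c(0.05, 0.0, 1.0),
    sit = c(0.9, 0.1, 0.35),
    lie = c(0.15, 0.95, 0.1)
  )
  grav <- grav / sqrt(sum(grav^2))
  wob <- wobble_amp * sin(2 * pi * 0.15 * t + stats::runif(1, 0, 2 * pi))
  rbind(grav[1] + wob, grav[2] + 0.5 * wob, grav[3] - 0.3 * wob)
}

#' Simulate a labelled activity-window dataset
#'
#' Generates raw bilateral accelerometer signal per subject and activity
#' (walking and stair/crutch gait via the gait generator; sitting,
#' standing and lying as noisy static postures), runs the real anatomical
#' calibration and feature extraction, and returns one labelled feature
#' row per 4-s window. Between-subject variation enters through stride
#' times, waveform amplitude, mounting tilt and posture wobble, so the
#' canonical features are informative but imperfect. Two pure-noise
#' feature columns are appended for selection tests.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param classes Activity classes (default all six).
#' @param windows_per_class 4-s windows per subject and class (default 10).
#' @param seed RNG seed.
#' @return Data frame: `subject`, `activity`, `label`
#'   (`walk` / `not_walk`), six canonical feature columns, and
#'   `noise_a`, `noise_b`.
#' @export
simulate_activity_windows <- function(n_subjects,
                                      classes = c("walk", "sit", "stand",
                                                  "lie", "stairs", "crutch"),
                                      windows_per_class = 10, seed = 1) {
  stopifnot(n_subjects >= 2)
  withr::with_seed(seed, {
    rate <- 31.25
    win_n <- round(4 * rate)
    rows <- list()
    for (s in seq_len(n_subjects)) {
      subj <- sprintf("SUBJ%02d", s)
      tilt <- stats::runif(1, 2, 15)
      for (cl in classes) {
        dur <- windows_per_class * 4
        if (cl == "walk") {
          st <- min(max(stats::rnorm(1, 1.10, 0.08), 0.95), 1.45)
          n_str <- ceiling(dur / st) + 4
          sub_seed <- (s * 1000 + match(cl, classes) * 17 + seed) %% .Machine$integer.max
          cfg <- gait_sim_config(stride_time = st, duty_factor = 0.62,
                                 n_strides = n_str, seed = sub_seed,
                                 mount_tilt_deg = tilt,
                                 noise_sd = 0.04)
          sim <- simulate_gait_recording(cfg)
          rec <- sim$recording
          cc_r <- sim$calibration$right$cc_axis
          cc_l <- sim$calibration$left$cc_axis
          wins <- partition_windows(rec)[seq_len(windows_per_class)]
        } else if (cl %in% c("stairs", "crutch")) {
          mounts <- list(right = rot_y(tilt * pi / 180),
                         left = rot_y(-tilt * pi / 180))
          tt <- seq(0, dur - 1 / rate, by = 1 / rate)
          ct <- if (cl == "stairs") stats::rnorm(1, 1.7, 0.12) else stats::rnorm(1, 2.1, 0.15)
          amp <- if (cl == "stairs") stats::runif(1, 0.45, 0.65) else stats::runif(1, 0.25, 0.45)
          coef_cc <- cc_cycle_coefficients(0.62)
          # crutch swing-through: legs share the cycle phase; stairs:
          # independent legs half a cycle apart
          ph0 <- if (cl == "crutch") c(right = 0, left = 0) else c(right = 0, left = 0.5)
          mk <- function(leg) {
            anat <- quasi_gait_block(tt, ct, amp, jitter_sd = 0.6,
                                     phase0 = ph0[[leg]], coef_cc, rate)
            sens <- t(mounts[[leg]] %*% anat) +
              matrix(stats::rnorm(length(tt) * 3, sd = 0.04), length(tt), 3)
            sensor_stream(sens, rate, leg, "accel")
          }
          dummy_emg <- function(leg) {
            ne <- round(dur * 250)
            sensor_stream(matrix(stats::rnorm(ne, sd = 0.01), ncol = 1),
                          250, leg, "semg")
          }
          rec <- bilateral_recording(mk("right"), mk("left"),
                                     dummy_emg("right"), dummy_emg("left"))
          cc_r <- mounts$right[, 3]
          cc_l <- mounts$left[, 3]
          wins <- partition_windows(rec)[seq_len(windows_per_class)]
        } else {
          mounts <- list(right = rot_y(tilt * pi / 180),
                         left = rot_y(-tilt * pi / 180))
          wobble <- stats::runif(1, 0.01, 0.05)
          tt <- seq(0, dur - 1 / rate, by = 1 / rate)
          mk <- function(leg) {
            anat <- static_posture_block(tt, cl, wobble)
            sens <- t(mounts[[leg]] %*% anat) +
              matrix(stats::rnorm(length(tt) * 3, sd = 0.03), length(tt), 3)
            sensor_stream(sens, rate, leg, "accel")
          }
          dummy_emg <- function(leg) {
            ne <- round(dur * 250)
            sensor_stream(matrix(stats::rnorm(ne, sd = 0.01), ncol = 1),
                          250, leg, "semg")
          }
          rec <- bilateral_recording(mk("right"), mk("left"),
                                     dummy_emg("right"), dummy_emg("left"))
          cc_r <- mounts$right[, 3]
          cc_l <- mounts$left[, 3]
          wins <- partition_windows(rec)[seq_len(windows_per_class)]
        }
        fm <- window_feature_matrix(wins, cc_r, cc_l, rate,
                                    features = canonical_features())
        fm$subject <- subj
        fm$activity <- cl
        fm$label <- if (cl == "walk") "walk" else "not_walk"
        rows[[length(rows) + 1]] <- fm
      }
    }
    out <- do.call(rbind, rows)
    out$window_index <- NULL
    out$noise_a <- stats::rnorm(nrow(out))
    subj_eff <- stats::rnorm(n_subjects)
    out$noise_b <- subj_eff[as.integer(factor(out$subject))] + stats::rnorm(nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a free-living subject-day
#'
#' Stitches walking bouts and rest (sit/stand) blocks, all aligned to the
#' 4-s window grid, into one continuous recording with ground truth
#' walking time and stride events.
#'
#' @param walk_bouts Number of walking bouts (default 5).
#' @param bout_s Walking bout length in s, multiple of 4 (default 120).
#' @param rest_s Rest block length in s, multiple of 4 (default 120).
#' @param cfg Base [gait_sim_config()]; its `n_strides` is overridden per
#'   bout to fill `bout_s`.
#' @param seed RNG seed (overrides `cfg$seed`).
#' @return List with `recording`, `calibration`, `truth` (walking spans,
#'   stride events, total walking seconds).
#' @export
simulate_day <- function(walk_bouts = 5, bout_s = 120, rest_s = 120,
                         cfg = gait_sim_config(), seed = cfg$seed) {
  stopifnot(bout_s %% 4 == 0, rest_s %% 4 == 0)
  withr::with_seed(seed, {
    fs_a <- cfg$rates$accel
    fs_e <- cfg$rates$semg
    blocks <- list()
    events <- list()
    walk_spans <- list()
    t_cursor <- 0
    calib <- NULL
    for (b in seq_len(walk_bouts)) {
      # rest block
      nr_a <- round(rest_s * fs_a)
      tt <- seq(0, rest_s - 1 / fs_a, by = 1 / fs_a)
      rest_accel <- lapply(c(right = "right", left = "left"), function(leg) {
        tiltm <- rot_y((if (leg == "right") 1 else -1) * cfg$mount_tilt_deg * pi / 180)
        anat <- static_posture_block(tt, if (b %% 2 == 0) "sit" else "stand", 0.03)
        t(tiltm %*% anat) + matrix(stats::rnorm(nr_a * 3, sd = cfg$noise_sd), nr_a, 3)
      })
      nr_e <- round(rest_s * fs_e)
      rest_emg <- lapply(c(right = "right", left = "left"), function(leg) {
        matrix(stats::rnorm(nr_e, sd = cfg$emg_noise_sd + 0.02), ncol = 1)
      })
      blocks[[length(blocks) + 1]] <- list(accel = rest_accel, semg = rest_emg)
      t_cursor <- t_cursor + rest_s

      # walking bout trimmed to exactly bout_s on the window grid
      n_str <- max(6L, floor(bout_s / cfg$stride_time) - 4L)
      bcfg <- cfg
      bcfg$n_strides <- n_str
      bcfg$seed <- (cfg$seed + 7919L * b) %% .Machine$integer.max
      sim <- simulate_gait_recording(bcfg)
      calib <- sim$calibration
      trim <- function(m, n) m[seq_len(n), , drop = FALSE]
      na <- round(bout_s * fs_a)
      ne <- round(bout_s * fs_e)
      full_na <- nrow(sim$recording$streams$accel_r$samples)
      if (full_na < na) stop("bout too short; increase n_strides", call. = FALSE)
      walk_accel <- list(right = trim(sim$recording$streams$accel_r$samples, na),
                         left = trim(sim$recording$streams$accel_l$samples, na))
      walk_emg <- list(right = trim(sim$recording$streams$semg_r$samples, ne),
                       left = trim(sim$recording$streams$semg_l$samples, ne))
      blocks[[length(blocks) + 1]] <- list(accel = walk_accel, semg = walk_emg)
      ev <- sim$truth$events
      ev <- ev[ev$t_next_contact <= bout_s, , drop = FALSE]
      ev[c("t_contact", "t_off", "t_next_contact")] <-
        ev[c("t_contact", "t_off", "t_next_contact")] + t_cursor
      events[[length(events) + 1]] <- ev
      walk_spans[[length(walk_spans) + 1]] <- c(t_cursor, t_cursor + bout_s)
      t_cursor <- t_cursor + bout_s
    }
    cat_streams <- function(part, leg, modality, rate) {
      m <- do.call(rbind, lapply(blocks, function(bl) bl[[part]][[leg]]))
      sensor_stream(m, rate, leg, modality,
                    range_limit = if (modality == "accel") 16 else Inf)
    }
    rec <- bilateral_recording(
      cat_streams("accel", "right", "accel", fs_a),
      cat_streams("accel", "left", "accel", fs_a),
      cat_streams("semg", "right", "semg", fs_e),
      cat_streams("semg", "left", "semg", fs_e),
      subject_id = cfg$subject_id
    )
    list(recording = rec, calibration = calib,
         truth = list(events = do.call(rbind, events),
                      walk_spans = do.call(rbind, walk_spans),
                      walking_time_s = walk_bouts * bout_s,
                      config = cfg))
  })
}
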