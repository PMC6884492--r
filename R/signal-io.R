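# Sensor stream containers and raw-data plumbing.
#
# A recording is four streams: tri-axial thigh acceleration (default
# 31.25 Hz, +/- 16 g range) and single-channel surface EMG (default 250 Hz)
# for each leg, time-aligned on a shared clock in seconds.

#' Construct a sensor stream
#'
#' @param samples Numeric matrix, one row per sample: 3 columns (x, y, z in
#'   g) for accelerometer streams, 1 column (mV) for sEMG.
#' @param rate Sampling rate in Hz.
#' @param leg `"right"` or `"left"`.
#' @param modality `"accel"` or `"semg"`.
#' @param range_limit Full-scale limit (g for accel, mV for sEMG);
#'   defaults to 16 g for accel, `Inf` for sEMG.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(samples, rate, leg = c("right", "left"),
                          modality = c("accel", "semg"),
                          range_limit = NULL, t0 = 0) {
  leg <- match.arg(leg)
  modality <- match.arg(modality)
  samples <- as.matrix(samples)
  ncol_exp <- if (modality == "accel") 3L else 1L
  if (ncol(samples) != ncol_exp) {
    stop(sprintf("%s stream must have %d channel(s)", modality, ncol_exp),
         call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive", call. = FALSE)
  if (is.null(range_limit)) range_limit <- if (modality == "accel") 16 else Inf
  structure(
    list(samples = samples, rate = rate, leg = leg, modality = modality,
         range_limit = range_limit, t0 = t0),
    class = "sensor_stream"
  )
}

stream_times <- function(s) s$t0 + (seq_len(nrow(s$samples)) - 1) / s$rate
stream_duration <- function(s) nrow(s$samples) / s$rate

#' Construct a bilateral recording
#'
#' Bundles the four synchronized streams of one subject-day.
#'
#' @param accel_r,accel_l,semg_r,semg_l [sensor_stream()] objects with
#'   matching legs/modalities.
#' @param subject_id Subject label.
#' @param start_time Optional wall-clock start (`POSIXct` or seconds since
#'   midnight) used only for time-of-day binning.
#' @param group Optional group label (`"T1"`, `"T2"`, `"C"`).
#' @return An object of class `bilateral_recording`.
#' @export
bilateral_recording <- function(accel_r, accel_l, semg_r, semg_l,
                                subject_id = "S01", start_time = NULL,
                                group = NULL) {
  streams <- list(accel_r = accel_r, accel_l = accel_l,
                  semg_r = semg_r, semg_l = semg_l)
  expect <- list(accel_r = c("right", "accel"), accel_l = c("left", "accel"),
                 semg_r = c("right", "semg"), semg_l = c("left", "semg"))
  for (nm in names(streams)) {
    s <- streams[[nm]]
    if (!inherits(s, "sensor_stream")) stop("streams must be sensor_stream objects", call. = FALSE)
    if (s$leg != expect[[nm]][1] || s$modality != expect[[nm]][2]) {
      stop(sprintf("stream %s has wrong leg/modality", nm), call. = FALSE)
    }
  }
  spans <- vapply(streams, function(s) c(s$t0, s$t0 + stream_duration(s)), numeric(2))
  if (max(spans[1, ]) >= min(spans[2, ])) {
    stop("streams do not overlap in time", call. = FALSE)
  }
  structure(
    list(streams = streams, subject_id = subject_id,
         start_time = start_time, group = group),
    class = "bilateral_recording"
  )
}

#' @export
print.bilateral_recording <- function(x, ...) {
  cat(sprintf("<bilateral_recording> subject %s\n", x$subject_id))
  for (nm in names(x$streams)) {
    s <- x$streams[[nm]]
    cat(sprintf("  %-8s %6.2f Hz  %8d samples  %7.1f s\n",
                nm, s$rate, nrow(s$samples), stream_duration(s)))
  }
  invisible(x)
}

#' Write a recording to long-format CSV
#'
#' One row per sample: `stream`, `t` (s), `v1`, `v2`, `v3` (`v2`/`v3`
#' empty for sEMG). Metadata (rates, ranges, subject) travels in a JSON
#' sidecar `<path>.meta.json`. This is the package's single on-disk
#' dialect; [load_recording()] reads it back losslessly.
#'
#' @param rec A [bilateral_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  rows <- lapply(names(rec$streams), function(nm) {
    s <- rec$streams[[nm]]
    v <- s$samples
    data.frame(stream = nm, t = stream_times(s),
               v1 = v[, 1],
               v2 = if (ncol(v) > 1) v[, 2] else NA_real_,
               v3 = if (ncol(v) > 2) v[, 3] else NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(
    subject_id = rec$subject_id,
    group = rec$group,
    start_time = if (is.null(rec$start_time)) NULL else as.numeric(rec$start_time),
    streams = lapply(rec$streams, function(s) {
      list(rate = s$rate, leg = s$leg, modality = s$modality,
           range_limit = s$range_limit, t0 = s$t0)
    })
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a recording from long-format CSV
#'
#' @param path CSV path written by [write_recording()] (or following the
#'   same layout).
#' @param layout Optional list overriding stream metadata when no sidecar
#'   exists: per-stream `rate`, `range_limit`. Rates absent from both are
#'   inferred from the median timestep.
#' @param tol Relative tolerance on timestamp uniformity (default 1e-3).
#' @return A [bilateral_recording()].
#' @export
load_recording <- function(path, layout = NULL, tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("stream", "t", "v1")
  if (!all(need %in% names(df))) {
    stop("format error: CSV must have columns stream, t, v1[, v2, v3]", call. = FALSE)
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  required <- c("accel_r", "accel_l", "semg_r", "semg_l")
  missing <- setdiff(required, unique(df$stream))
  if (length(missing)) {
    stop("format error: missing stream(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  streams <- lapply(required, function(nm) {
    sub <- df[df$stream == nm, , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    modality <- if (grepl("^accel", nm)) "accel" else "semg"
    leg <- if (grepl("_r$", nm)) "right" else "left"
    if (modality == "accel" &&
        (!all(c("v2", "v3") %in% names(sub)) || anyNA(sub$v2) || anyNA(sub$v3))) {
      stop("format error: accel stream ", nm, " lacks 3 channels", call. = FALSE)
    }
    m <- meta$streams[[nm]]
    lay <- layout[[nm]]
    dt <- diff(sub$t)
    rate <- if (!is.null(m$rate)) m$rate else if (!is.null(lay$rate)) lay$rate else 1 / stats::median(dt)
    if (length(dt) && max(abs(dt - 1 / rate)) > tol / rate) {
      stop("sampling error: non-uniform timestamps in stream ", nm, call. = FALSE)
    }
    range_limit <- if (!is.null(m$range_limit)) m$range_limit
      else if (!is.null(lay$range_limit)) lay$range_limit
      else if (modality == "accel") 16 else Inf
    samples <- if (modality == "accel") as.matrix(sub[, c("v1", "v2", "v3")]) else matrix(sub$v1, ncol = 1)
    dimnames(samples) <- NULL
    sensor_stream(samples, rate, leg, modality, range_limit, t0 = sub$t[1])
  })
  names(streams) <- required
  bilateral_recording(streams$accel_r, streams$accel_l,
                      streams$semg_r, streams$semg_l,
                      subject_id = if (!is.null(meta$subject_id)) meta$subject_id else "S01",
                      start_time = meta$start_time,
                      group = meta$group)
}

#' Partition a recording into 4-second analysis windows
#'
#' Windows are non-overlapping and contiguous; a trailing remainder
#' shorter than the window is discarded. Windowing is aligned to the start
#' of the common time span of all four streams.
#'
#' @param rec A [bilateral_recording()].
#' @param window_s Window length in seconds (default 4).
#' @return A list of `analysis_window` objects, each holding the window
#'   `index`, `start`/`end` times and per-leg raw accel segments
#'   (`accel_R`, `accel_L`, matrices) plus sample index ranges for the
#'   sEMG streams.
#' @export
partition_windows <- function(rec, window_s = 4) {
  t_start <- max(vapply(rec$streams, function(s) s$t0, numeric(1)))
  t_end <- min(vapply(rec$streams, function(s) s$t0 + stream_duration(s), numeric(1)))
  n_win <- floor((t_end - t_start) / window_s)
  if (n_win < 1) return(list())
  lapply(seq_len(n_win), function(i) {
    ws <- t_start + (i - 1) * window_s
    we <- ws + window_s
    seg <- function(nm) {
      s <- rec$streams[[nm]]
      i0 <- round((ws - s$t0) * s$rate) + 1
      n <- round(window_s * s$rate)
      s$samples[i0:(i0 + n - 1), , drop = FALSE]
    }
    structure(
      list(index = i, start = ws, end = we,
           accel_R = seg("accel_r"), accel_L = seg("accel_l"),
           semg_R = seg("semg_r"), semg_L = seg("semg_l")),
      class = "analysis_window"
    )
  })
}

#' Detect amplitude clipping in a signal segment
#'
#' A segment clips when at least `k` consecutive samples sit within
#' `eps_frac * range_limit` of either rail on any channel. Walking bouts
#' containing clipped accelerometer or sEMG data are discarded downstream.
#'
#' @param segment Numeric vector or matrix of samples.
#' @param range_limit Full-scale value (the rail magnitude).
#' @param k Minimum run length (default 3).
#' @param eps_frac Rail tolerance as a fraction of `range_limit`
#'   (default 0.01).
#' @return `TRUE` if clipping is present.
#' @export
detect_clipping <- function(segment, range_limit, k = 3, eps_frac = 0.01) {
  if (!is.finite(range_limit)) return(FALSE)
  m <- as.matrix(segment)
  if (nrow(m) == 0) stop("empty segment", call. = FALSE)
  thr <- range_limit * (1 - eps_frac)
  for (j in seq_len(ncol(m))) {
    at_rail <- abs(m[, j]) >= thr
    if (!any(at_rail)) next
    r <- rle(at_rail)
    if (any(r$lengths[r$values] >= k)) return(TRUE)
  }
  FALSE
}
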