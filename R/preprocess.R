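# Preprocessing chain: trim -> (axis select) -> resample to 200 Hz ->
# median filter (window 5) -> zero-phase 4th-order Butterworth low-pass.

signal_columns <- function(rec) setdiff(names(rec), "time_s")

#' Validate a raw recording and infer its sampling rate
#'
#' A recording is a tibble with a monotone `time_s` column and one or more
#' numeric signal columns, sampled uniformly. The sampling rate is inferred
#' as the reciprocal of the median sample interval and stored in
#' `attr(rec, "fs")`.
#'
#' @param df A data frame with `time_s` plus signal columns.
#' @param fs Optional known sampling rate (Hz); checked against the time
#'   column when given.
#' @return The validated recording tibble with an `fs` attribute.
#' @export
as_recording <- function(df, fs = NULL) {
  if (!"time_s" %in% names(df) || ncol(df) < 2L)
    abort("A recording needs a `time_s` column and at least one signal column.",
          class = "gaitcog_format")
  if (nrow(df) < 2L)
    abort("A recording needs at least two samples.", class = "gaitcog_format")
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    abort("`time_s` must be strictly increasing.", class = "gaitcog_format")
  med <- median(dt)
  if (max(abs(dt - med)) > 0.01 * med)
    abort("Non-uniform sampling: intervals deviate more than 1% from the median.",
          class = "gaitcog_format")
  fs_inf <- 1 / med
  if (!is.null(fs) && abs(fs - fs_inf) > 0.01 * fs_inf)
    abort("Declared sampling rate disagrees with the time column.",
          class = "gaitcog_format")
  rec <- tibble::as_tibble(df)
  attr(rec, "fs") <- fs %||% fs_inf
  rec
}

rec_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (is.null(fs)) fs <- 1 / median(diff(rec$time_s))
  fs
}

keep_attrs <- function(new, old, fs = rec_fs(old), extra_prov = NULL) {
  attr(new, "fs") <- fs
  attr(new, "meta") <- attr(old, "meta")
  attr(new, "provenance") <- c(attr(old, "provenance"), extra_prov)
  new
}

#' Trim a recording to a time window
#'
#' Keeps samples in the closed-open window `[t_start, t_end)`, measured
#' relative to the first sample. This mirrors the manual selection step in
#' which data recorded before and after the walking task is removed.
#'
#' @param rec A recording tibble (see [as_recording()]).
#' @param t_start,t_end Window bounds in seconds, `0 <= t_start < t_end <=
#'   duration`.
#' @return The trimmed recording.
#' @export
trim_recording <- function(rec, t_start, t_end) {
  t0 <- rec$time_s[1]
  duration <- rec$time_s[nrow(rec)] - t0 + 1 / rec_fs(rec)
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_start < 0 ||
        t_start >= t_end || t_end > duration + 1e-9)
    abort(sprintf("Trim window [%s, %s) is outside the recording (duration %.3f s).",
                  t_start, t_end, duration),
          class = "gaitcog_range")
  out <- rec[rec$time_s - t0 >= t_start & rec$time_s - t0 < t_end, ]
  keep_attrs(out, rec, extra_prov = list(trim = c(t_start, t_end)))
}

#' Select the analysis axis of a multi-axis recording
#'
#' Gait events are detected on a single sagittal-plane channel. For
#' multi-axis files the default picks the axis with the greatest variance
#' over the walk; a specific axis can be forced by name.
#'
#' @param rec A recording tibble.
#' @param axis Optional signal column name.
#' @return A single-axis recording with columns `time_s`, `signal`.
#' @export
select_axis <- function(rec, axis = NULL) {
  cols <- signal_columns(rec)
  if (is.null(axis)) {
    axis <- cols[which.max(vapply(cols, function(cc) stats::var(rec[[cc]]), 0))]
  } else if (!axis %in% cols) {
    abort(sprintf("Axis '%s' not found in recording.", axis),
          class = "gaitcog_format")
  }
  out <- tibble::tibble(time_s = rec$time_s, signal = rec[[axis]])
  keep_attrs(out, rec, extra_prov = list(axis = axis))
}

# Split a decimation factor into stages of at most 10 so the anti-alias
# filters stay numerically comfortable at very high input rates.
decimation_stages <- function(f) {
  stages <- integer()
  while (f > 10L) {
    d <- max(which(f %% (2:10) == 0) + 1L, 1L)
    if (d <= 1L) break   # large prime factor: single stage
    stages <- c(stages, d)
    f <- f %/% d
  }
  c(stages, f)
}

#' Resample a recording to 200 Hz
#'
#' Down-samples from any rate of at least 200 Hz. Integer decimation
#' factors use a zero-phase Butterworth anti-alias filter followed by
#' sample picking (staged for large factors); rational factors fall back to
#' polyphase resampling. Upsampling is refused.
#'
#' @param rec A recording tibble.
#' @param to_hz Target rate, default 200 Hz.
#' @return The recording at `to_hz`, duration preserved within one sample
#'   period.
#' @export
resample_recording <- function(rec, to_hz = 200) {
  fs <- rec_fs(rec)
  if (fs < to_hz - 1e-6)
    abort(sprintf("Cannot upsample: input rate %.1f Hz is below %s Hz.", fs, to_hz),
          class = "gaitcog_unsupported_rate")
  if (abs(fs - to_hz) < 1e-6) return(rec)
  cols <- signal_columns(rec)
  ratio <- fs / to_hz
  t0 <- rec$time_s[1]
  if (abs(ratio - round(ratio)) < 1e-6) {
    vals <- rec[cols]
    f <- as.integer(round(ratio))
    for (stage in decimation_stages(f)) {
      fs_in <- to_hz * f
      bf <- signal::butter(4, (0.45 * fs_in / stage) / (fs_in / 2), type = "low")
      keep <- seq(1, nrow(vals), by = stage)
      vals <- tibble::as_tibble(lapply(vals, function(x)
        filtfilt_padded(bf, x)[keep]))
      f <- f %/% stage
    }
    out <- dplyr::bind_cols(
      tibble::tibble(time_s = t0 + (seq_len(nrow(vals)) - 1) / to_hz), vals)
  } else {
    # rational ratio: polyphase resampling
    pq <- rational_ratio(to_hz, fs)
    vals <- lapply(rec[cols], function(x)
      as.numeric(signal::resample(x, pq[1], pq[2])))
    out <- dplyr::bind_cols(
      tibble::tibble(time_s = t0 + (seq_along(vals[[1]]) - 1) / to_hz),
      tibble::as_tibble(vals))
  }
  keep_attrs(out, rec, fs = to_hz, extra_prov = list(resampled_from = fs))
}

rational_ratio <- function(p, q, tol = 1e-6) {
  for (den in 1:1000) {
    num <- p / q * den
    if (abs(num - round(num)) < tol) return(c(round(num), den))
  }
  abort("Sampling-rate ratio is not a small rational number.",
        class = "gaitcog_unsupported_rate")
}

# Zero-phase filtering with even reflection padding at both ends, so the
# filter warm-up transient falls on the padded copies, not the data.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 600L)
  xp <- c(rev(x[2:(np + 1)]), x, rev(x[(n - np):(n - 1)]))
  as.numeric(signal::filtfilt(bf, xp))[(np + 1):(np + n)]
}

# Window-5 running median with reflect padding, so boundaries never
# fabricate extremes.
median5 <- function(x, window = 5L) {
  k <- (window - 1L) %/% 2L
  pad <- c(x[(k + 1):2], x, x[(length(x) - 1):(length(x) - k)])
  as.numeric(stats::runmed(pad, window))[(k + 1):(k + length(x))]
}

#' Smooth a 200 Hz recording
#'
#' Applies the fixed filter chain used ahead of event detection: a running
#' median of window 5 samples (suppressing single-sample spikes) followed
#' by a 4th-order Butterworth low-pass applied forward-backward
#' (zero-phase, so event timestamps are not lagged). The unfiltered input
#' is kept alongside as `signal_raw` because the complexity index is
#' computed on the unsmoothed 200 Hz signal.
#'
#' @param rec A single-axis recording at 200 Hz.
#' @param cutoff_hz Low-pass cutoff in Hz. Gait energy sits below ~10 Hz,
#'   the default.
#' @param median_window Median filter window in samples (odd).
#' @return A tibble with `time_s`, `signal` (smoothed) and `signal_raw`.
#' @export
smooth_recording <- function(rec, cutoff_hz = 10, median_window = 5L) {
  fs <- rec_fs(rec)
  if (abs(fs - 200) > 1)
    abort("`smooth_recording()` expects a 200 Hz recording; resample first.",
          class = "gaitcog_unsupported_rate")
  cols <- signal_columns(rec)
  if (length(cols) > 1L) rec <- select_axis(rec)
  x <- rec[[signal_columns(rec)[1]]]
  if (length(x) < 15L)
    abort("Signal shorter than the filter warm-up (15 samples).",
          class = "gaitcog_range")
  xm <- median5(x, median_window)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  sm <- filtfilt_padded(bf, xm)
  out <- tibble::tibble(time_s = rec$time_s, signal = sm, signal_raw = x)
  keep_attrs(out, rec, fs = fs,
             extra_prov = list(median_window = median_window,
                               butterworth = c(order = 4, cutoff_hz = cutoff_hz)))
}

#' Run the full preprocessing chain on a raw recording
#'
#' Fixed order: trim, axis selection, resample to 200 Hz, median filter,
#' zero-phase Butterworth low-pass.
#'
#' @param rec A recording tibble.
#' @param trim Optional `c(t_start, t_end)` window in seconds.
#' @param axis Optional signal column name (default: greatest variance).
#' @param cutoff_hz Butterworth low-pass cutoff, Hz.
#' @return A clean 200 Hz tibble with `signal` and `signal_raw` columns.
#' @export
preprocess_recording <- function(rec, trim = NULL, axis = NULL, cutoff_hz = 10) {
  if (!is.null(trim)) rec <- trim_recording(rec, trim[1], trim[2])
  rec <- select_axis(rec, axis)
  rec <- resample_recording(rec)
  smooth_recording(rec, cutoff_hz = cutoff_hz)
}
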