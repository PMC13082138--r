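#' Band-pass filter specification
#'
#' Defaults follow the pipeline's standard preprocessing: an order-4
#' Butterworth band-pass with cutoffs at 0.05 Hz (removes sensor drift and
#' the gravity DC component) and 2 Hz (removes vibration noise above the
#' dominant band of human trunk movement). `zero_phase` applies the filter
#' forward and backward (no phase delay, squared magnitude response);
#' `causal` applies a single forward pass and is usable in streaming.
#'
#' @param low_hz High-pass cutoff in Hz (>= 0; 0 disables the high-pass).
#' @param high_hz Low-pass cutoff in Hz.
#' @param order Butterworth order of the single-pass design.
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.05, high_hz = 2, order = 4L,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (!is.finite(low_hz) || low_hz < 0) stop("low_hz must be >= 0")
  if (!is.finite(high_hz) || high_hz <= low_hz)
    stop("high_hz must exceed low_hz")
  if (order < 1) stop("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), mode = mode),
            class = "filter_spec")
}

# apply a signal::Arma-style filter in the requested mode
apply_filt <- function(filt, x, mode) {
  if (mode == "zero_phase") as.numeric(signal::filtfilt(filt, x))
  else as.numeric(signal::filter(filt, x))
}

#' Butterworth band-pass filter a recording
#'
#' Each axis is filtered independently. With `mode = "zero_phase"` the
#' filter is applied forward and backward, giving zero phase delay and an
#' effective magnitude order of twice the design order; `mode = "causal"`
#' applies a single forward pass whose gain at each cutoff is -3 dB.
#'
#' @param recording An [accel_recording].
#' @param spec A [filter_spec]; `high_hz` must be below the Nyquist
#'   frequency of the recording.
#' @return A filtered [accel_recording].
#' @export
#' @examples
#' rec <- accel_recording("s1", seq(0, 20, by = 0.02),
#'                        x = sin(2 * pi * seq(0, 20, by = 0.02)),
#'                        y = rep(0.5, 1001), z = rep(0, 1001))
#' filt <- bandpass(rec, filter_spec())
#' mean(filt$y)  # DC removed
bandpass <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "accel_recording"),
            inherits(spec, "filter_spec"))
  fs <- recording$sampling_rate_hz
  nyq <- fs / 2
  if (spec$high_hz >= nyq)
    stop("high_hz (", spec$high_hz, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  filt <- if (spec$low_hz > 0) {
    signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                   type = "pass")
  } else {
    signal::butter(spec$order, spec$high_hz / nyq, type = "low")
  }
  out <- recording
  out$x <- apply_filt(filt, recording$x, spec$mode)
  out$y <- apply_filt(filt, recording$y, spec$mode)
  out$z <- apply_filt(filt, recording$z, spec$mode)
  out
}

#' Vector magnitude of a (filtered) recording
#'
#' Collapses the three axes into the Euclidean norm
#' `sqrt(x^2 + y^2 + z^2)` at each time point, the orientation-invariant
#' movement-intensity signal used by the cut-point classifier.
#'
#' @param recording An [accel_recording], normally already band-passed.
#' @return An object of class `magnitude_series` with fields `t`, `m`,
#'   `sampling_rate_hz`, `subject_id`.
#' @export
magnitude <- function(recording) {
  stopifnot(inherits(recording, "accel_recording"))
  structure(list(subject_id = recording$subject_id,
                 sampling_rate_hz = recording$sampling_rate_hz,
                 t = recording$t,
                 m = sqrt(recording$x^2 + recording$y^2 + recording$z^2)),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> subject %s: %d samples, median %.4f g\n",
              x$subject_id, length(x$m), stats::median(x$m)))
  invisible(x)
}

#' Centered rolling median of a magnitude series
#'
#' The window width is `N = round(window_s * sampling_rate)` samples,
#' centered on each sample (for even N the window extends one sample
#' further into the future). Edges use the truncated available window
#' (minimum 1 sample). When the centered output is consumed causally the
#' value at time `t` corresponds to `t - (N - 1) / (2 fs)`, a fixed delay
#' of `(N - 1) / 2` samples: about 2.5 s for the default 5-s window at
#' 50 Hz.
#'
#' @param series A `magnitude_series` (or any list with numeric `m` and
#'   `sampling_rate_hz`).
#' @param window_s Window duration in seconds; must span at least 3
#'   samples.
#' @return A `magnitude_series` of the same length with smoothed values.
#' @export
rolling_median <- function(series, window_s = 5) {
  n_win <- round(window_s * series$sampling_rate_hz)
  if (n_win < 3) stop("rolling window must span at least 3 samples")
  out <- series
  out$m <- roll_median_c(as.numeric(series$m), as.integer(n_win))
  out
}

#' Keep only the last portion of a recording
#'
#' Retains samples with `t >= t_end - 60 * minutes`, excluding
#' non-protocol activity (setup, calibration) at the start of long
#' recordings. Recordings shorter than the budget are returned whole.
#' Label intervals are clipped to the retained span.
#'
#' @param recording An [accel_recording].
#' @param labels A [label_track] on the same time base.
#' @param minutes Duration to keep, in minutes (default 20).
#' @return A list with elements `recording` and `labels`.
#' @export
truncate_last <- function(recording, labels, minutes = 20) {
  stopifnot(inherits(recording, "accel_recording"),
            inherits(labels, "label_track"))
  t_end <- recording$t[length(recording$t)]
  t_cut <- t_end - 60 * minutes
  if (recording$t[1L] >= t_cut)
    return(list(recording = recording, labels = labels))
  keep <- recording$t >= t_cut
  rec <- accel_recording(recording$subject_id, recording$t[keep],
                         recording$x[keep], recording$y[keep],
                         recording$z[keep],
                         sampling_rate_hz = recording$sampling_rate_hz)
  iv <- labels$intervals
  iv <- iv[iv$end_s > t_cut, , drop = FALSE]
  if (nrow(iv) == 0L) stop("no label intervals in the retained span")
  iv$start_s <- pmax(iv$start_s, t_cut)
  lab <- label_track(labels$subject_id, iv$start_s, iv$end_s, iv$activity)
  list(recording = rec, labels = lab)
}

#' Downsample a recording to a lower sampling rate
#'
#' Anti-alias low-pass filtering (zero-phase order-4 Butterworth at 0.8x
#' the new Nyquist frequency, i.e. an 8th-order magnitude response)
#' followed by decimation by the integer rate ratio. Requesting the
#' native rate is the identity.
#'
#' @param recording An [accel_recording].
#' @param target_hz Target rate; must divide the native rate.
#' @return An [accel_recording] at `target_hz`.
#' @export
resample_accel <- function(recording, target_hz) {
  stopifnot(inherits(recording, "accel_recording"))
  fs <- recording$sampling_rate_hz
  if (target_hz > fs) stop("target_hz exceeds the native rate")
  ratio <- fs / target_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("native rate ", fs, " Hz is not an integer multiple of ",
         target_hz, " Hz")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(recording)
  aa <- signal::butter(4, 0.8 * (target_hz / 2) / (fs / 2), type = "low")
  idx <- seq(1L, length(recording$t), by = ratio)
  accel_recording(recording$subject_id, recording$t[idx],
                  as.numeric(signal::filtfilt(aa, recording$x))[idx],
                  as.numeric(signal::filtfilt(aa, recording$y))[idx],
                  as.numeric(signal::filtfilt(aa, recording$z))[idx],
                  sampling_rate_hz = target_hz)
}

#' Cut a labeled recording into fixed-duration windows
#'
#' Windows of `window_s` seconds are placed every `stride_s` seconds
#' (non-overlapping by default). Each window is labeled by the activity of
#' the interval covering its final sample (the most-recent-activity rule).
#' Windows overlapping a `transition` or `interference` interval, or
#' containing unlabeled samples, are excluded and tallied in
#' `excluded_counts` instead.
#'
#' @param recording An [accel_recording] (normally filtered and, for the
#'   CNN, resampled first).
#' @param labels A [label_track] on the same time base.
#' @param window_s Window duration in seconds (default 5).
#' @param stride_s Stride between window ends in seconds (default
#'   `window_s`, i.e. non-overlapping).
#' @return An object of class `window_set`: `samples` is an
#'   `n x window_len x 3` array, `label` a factor over the five activity
#'   classes, `end_time_s` / `end_index` locate each window, and
#'   `excluded_counts` tallies exclusions by reason.
#' @export
segment_windows <- function(recording, labels, window_s = 5,
                            stride_s = window_s) {
  stopifnot(inherits(recording, "accel_recording"),
            inherits(labels, "label_track"))
  fs <- recording$sampling_rate_hz
  n <- length(recording$t)
  win_len <- round(window_s * fs)
  stride <- max(1L, round(stride_s * fs))
  excluded <- c(transition = 0L, interference = 0L, unlabeled = 0L)
  if (win_len > n) {
    warning("window (", window_s, " s) longer than recording; no windows")
    return(empty_window_set(recording, window_s, stride_s, win_len, excluded))
  }
  ends <- seq(win_len, n, by = stride)
  iv <- labels$intervals
  keep_end <- integer(0)
  lab <- character(0)
  for (e in ends) {
    t_lo <- recording$t[e - win_len + 1L]
    t_hi <- recording$t[e]
    over <- which(iv$start_s < t_hi & iv$end_s > t_lo)
    acts <- iv$activity[over]
    if ("transition" %in% acts) {
      excluded[["transition"]] <- excluded[["transition"]] + 1L
    } else if ("interference" %in% acts) {
      excluded[["interference"]] <- excluded[["interference"]] + 1L
    } else {
      # uncovered span within the window => unlabeled
      covered <- length(over) > 0L &&
        min(iv$start_s[over]) <= t_lo + 1e-9 &&
        max(iv$end_s[over]) >= t_hi - 1e-9 &&
        (length(over) == 1L ||
           all(iv$start_s[over][-1L] <= iv$end_s[over][-length(over)] + 1e-9))
      final <- which(iv$start_s <= t_hi & iv$end_s > t_hi)
      if (length(final) == 0L)  # window ending exactly at the last interval end
        final <- which(abs(iv$end_s - t_hi) < 1e-9)
      if (!covered || length(final) == 0L) {
        excluded[["unlabeled"]] <- excluded[["unlabeled"]] + 1L
      } else {
        keep_end <- c(keep_end, e)
        lab <- c(lab, iv$activity[final[length(final)]])
      }
    }
  }
  n_keep <- length(keep_end)
  samples <- array(NA_real_, dim = c(n_keep, win_len, 3L))
  if (n_keep) {
    offs <- seq_len(win_len) - win_len
    for (i in seq_len(n_keep)) {
      idx <- keep_end[i] + offs
      samples[i, , 1L] <- recording$x[idx]
      samples[i, , 2L] <- recording$y[idx]
      samples[i, , 3L] <- recording$z[idx]
    }
  }
  structure(
    list(subject_id = recording$subject_id, window_s = window_s,
         stride_s = stride_s, sampling_rate_hz = fs, window_len = win_len,
         end_time_s = recording$t[keep_end], end_index = keep_end,
         samples = samples,
         label = factor(lab, levels = activity_classes()),
         excluded_counts = excluded),
    class = "window_set")
}

empty_window_set <- function(recording, window_s, stride_s, win_len, excluded) {
  structure(
    list(subject_id = recording$subject_id, window_s = window_s,
         stride_s = stride_s, sampling_rate_hz = recording$sampling_rate_hz,
         window_len = win_len, end_time_s = numeric(0),
         end_index = integer(0),
         samples = array(numeric(0), dim = c(0L, win_len, 3L)),
         label = factor(character(0), levels = activity_classes()),
         excluded_counts = excluded),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> subject %s: %d windows of %g s @ %g Hz (%d samples)\n",
    x$subject_id, length(x$label), x$window_s, x$sampling_rate_hz,
    x$window_len))
  if (length(x$label)) print(table(droplevels(x$label)))
  cat("excluded:", paste(names(x$excluded_counts), x$excluded_counts,
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}
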