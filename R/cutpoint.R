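#' Cut-point classifier configuration
#'
#' The default threshold of 0.07 g on the 5-s rolling median of the
#' band-passed vector magnitude separates active (walking, jogging) from
#' inactive (lying, sitting, standing) states. The alternative `mad`
#' metric applies a published Mean Amplitude Deviation cut-point of
#' 47.73 mG (0.04773 g) over the same 5-s rolling window.
#'
#' @param threshold_g Threshold on the rolling-median magnitude, in g.
#' @param window_s Rolling window duration in seconds.
#' @param metric `"magnitude_median"` (default) or `"mad"`.
#' @param mad_threshold_g Threshold for the MAD metric, in g.
#' @return An object of class `cutpoint_config`.
#' @export
cutpoint_config <- function(threshold_g = 0.07, window_s = 5,
                            metric = c("magnitude_median", "mad"),
                            mad_threshold_g = 0.04773) {
  metric <- match.arg(metric)
  if (!is.finite(threshold_g) || threshold_g <= 0)
    stop("threshold_g must be positive")
  if (!is.finite(window_s) || window_s <= 0)
    stop("window_s must be positive")
  structure(list(threshold_g = threshold_g, window_s = window_s,
                 metric = metric, mad_threshold_g = mad_threshold_g),
            class = "cutpoint_config")
}

#' Binary active/inactive classification of a magnitude series
#'
#' With `metric = "magnitude_median"` the input is expected to be a
#' rolling-median magnitude series (see [rolling_median()]) and is
#' thresholded directly; with `metric = "mad"` the input is the raw
#' magnitude and the rolling Mean Amplitude Deviation is computed
#' internally. A sample is `active` when the metric value is strictly
#' greater than the threshold (values exactly at the threshold are
#' `inactive`).
#'
#' @param series A `magnitude_series`.
#' @param config A [cutpoint_config].
#' @return An object of class `binary_series` with fields `t` and `state`
#'   (factor with levels `inactive`, `active`).
#' @export
classify_activity_level <- function(series, config = cutpoint_config()) {
  stopifnot(inherits(config, "cutpoint_config"))
  if (config$metric == "mad") {
    vals <- rolling_mad(series, config$window_s)$m
    thr <- config$mad_threshold_g
  } else {
    vals <- series$m
    thr <- config$threshold_g
  }
  binary_series(series$t, vals > thr, subject_id = series$subject_id)
}

binary_series <- function(t, active, subject_id = NULL) {
  structure(list(subject_id = subject_id, t = t,
                 state = factor(ifelse(active, "active", "inactive"),
                                levels = c("inactive", "active"))),
            class = "binary_series")
}

#' Rolling Mean Amplitude Deviation
#'
#' Per centered window `W`, `MAD(W) = mean(|m_i - mean(W)|)`: the mean
#' absolute deviation of the magnitude around its window mean, the
#' intensity metric of the comparison cut-point method. Window centering
#' and edge truncation follow [rolling_median()].
#'
#' @inheritParams rolling_median
#' @return A `magnitude_series` of rolling MAD values.
#' @export
rolling_mad <- function(series, window_s = 5) {
  n_win <- round(window_s * series$sampling_rate_hz)
  if (n_win < 3) stop("rolling window must span at least 3 samples")
  out <- series
  out$m <- roll_mad_c(as.numeric(series$m), as.integer(n_win))
  out
}

#' Map five-class activity labels to the binary outcome
#'
#' Lying, sitting and standing are inactive (standing involves little
#' chest-level movement and is conventionally grouped with the sedentary
#' states); walking and jogging are active.
#'
#' @param labels Factor or character vector of activity labels.
#' @return Factor with levels `inactive`, `active`.
#' @export
binary_truth <- function(labels) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), activity_classes())
  if (length(unknown))
    stop("not an activity label: ", paste(unknown, collapse = ", "))
  factor(ifelse(labels %in% c("walking", "jogging"), "active", "inactive"),
         levels = c("inactive", "active"))
}

#' Rolling-magnitude value of each window
#'
#' Looks up the smoothed magnitude at each window's final sample, the
#' per-window summary used for calibration and window-level binary
#' classification.
#'
#' @param windows A `window_set` (see [segment_windows()]).
#' @param med_series The rolling-median `magnitude_series` on the same
#'   sample grid as the recording the windows were cut from.
#' @return Numeric vector, one value per retained window.
#' @export
window_magnitudes <- function(windows, med_series) {
  stopifnot(inherits(windows, "window_set"))
  if (length(med_series$m) < max(c(0L, windows$end_index)))
    stop("magnitude series shorter than the windowed recording")
  med_series$m[windows$end_index]
}

#' Calibrate the cut-point threshold by distribution overlap
#'
#' Builds the empirical distributions of window-level rolling-magnitude
#' values for the inactive (lying, sitting, standing) and active
#' (walking, jogging) classes and scans a fixed grid of candidate
#' thresholds (0.001 g steps over the pooled value range), returning the
#' threshold that minimizes the number of misclassified windows (inactive
#' windows above the threshold plus active windows at or below it). Ties
#' are broken toward the smaller threshold.
#'
#' @param values Numeric vector of window-level rolling-magnitude values.
#' @param labels Activity labels of the same windows (five-class factor or
#'   character), mapped to binary via [binary_truth()].
#' @param step Grid step in g (default 0.001).
#' @return A list with `threshold` and `overlap_count` (the minimized
#'   misclassified-window count).
#' @export
calibrate_threshold <- function(values, labels, step = 0.001) {
  truth <- binary_truth(labels)
  if (length(values) != length(truth))
    stop("values and labels must have the same length")
  if (nlevels(droplevels(truth)) < 2L)
    stop("cannot calibrate with a single class")
  grid <- seq(min(values), max(values), by = step)
  active <- truth == "active"
  # misclassified(th) = #(inactive & value > th) + #(active & value <= th)
  sv <- sort(values[!active])
  sa <- sort(values[active])
  n_inact_above <- length(sv) - findInterval(grid, sv)
  n_act_below <- findInterval(grid, sa)
  miss <- n_inact_above + n_act_below
  i <- which.min(miss)  # first minimum = smallest threshold
  list(threshold = grid[i], overlap_count = as.integer(miss[i]))
}

#' Confusion-matrix metrics for binary activity classification
#'
#' `active` is the positive class. When no positives are predicted,
#' precision is reported as 0 (rather than undefined), matching the
#' convention used when the MAD baseline predicts no active windows.
#' `f1` is the harmonic mean of precision and recall and is 0 whenever
#' either is 0.
#'
#' @param pred,truth `binary_series` objects or factors/characters with
#'   levels `inactive`/`active`, equal length.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate_binary <- function(pred, truth) {
  pred <- as_binary_factor(pred)
  truth <- as_binary_factor(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  tp <- sum(pred == "active" & truth == "active")
  fp <- sum(pred == "active" & truth == "inactive")
  fn <- sum(pred == "inactive" & truth == "active")
  tn <- sum(pred == "inactive" & truth == "inactive")
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(pred), precision = precision,
       recall = recall, f1 = f1)
}

as_binary_factor <- function(x) {
  if (inherits(x, "binary_series")) x <- x$state
  factor(as.character(x), levels = c("inactive", "active"))
}

#' Seeded subject-level train/test split
#'
#' Splits subjects (not windows) so that no participant appears in both
#' sets, reproducing an 80/20 held-out-subject evaluation protocol.
#'
#' @param subjects Character vector of subject ids.
#' @param train_frac Fraction of subjects assigned to training.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
subject_split <- function(subjects, train_frac = 0.8, seed = 1L) {
  subjects <- unique(as.character(subjects))
  if (length(subjects) < 2L) stop("need at least 2 subjects to split")
  n_train <- max(1L, min(length(subjects) - 1L,
                         round(train_frac * length(subjects))))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  train <- sort(sample(subjects, n_train))
  list(train = train, test = sort(setdiff(subjects, train)))
}

#' Per-window cut-point classification of one labeled recording
#'
#' Convenience pipeline: truncate to the last `minutes`, band-pass
#' filter, take the vector magnitude and its rolling median, cut labeled
#' windows, and threshold the per-window value. Returns one row per
#' retained window.
#'
#' @param recording An [accel_recording].
#' @param labels A [label_track].
#' @param config A [cutpoint_config].
#' @param spec A [filter_spec].
#' @param minutes Truncation budget in minutes (default 20).
#' @return Data frame with columns `end_time_s`, `value`, `label`,
#'   `truth`, `pred`; `excluded_counts` attached as an attribute.
#' @export
cutpoint_windows <- function(recording, labels, config = cutpoint_config(),
                             spec = filter_spec(), minutes = 20) {
  tr <- truncate_last(recording, labels, minutes)
  filt <- bandpass(tr$recording, spec)
  med <- rolling_median(magnitude(filt), config$window_s)
  ws <- segment_windows(filt, tr$labels, window_s = config$window_s)
  vals <- window_magnitudes(ws, med)
  thr <- if (config$metric == "mad") config$mad_threshold_g else config$threshold_g
  if (config$metric == "mad") {
    mad <- rolling_mad(magnitude(filt), config$window_s)
    vals <- window_magnitudes(ws, mad)
  }
  out <- data.frame(end_time_s = ws$end_time_s, value = vals,
                    label = as.character(ws$label),
                    truth = binary_truth(ws$label),
                    pred = factor(ifelse(vals > thr, "active", "inactive"),
                                  levels = c("inactive", "active")),
                    stringsAsFactors = FALSE)
  attr(out, "excluded_counts") <- ws$excluded_counts
  out
}
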