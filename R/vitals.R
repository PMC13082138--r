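#' Resting heart-rate baseline
#'
#' The baseline is the median heart rate over samples falling inside
#' `lying` or `sitting` intervals that end no later than the first
#' `walking` interval's start. If the record contains no walking at all,
#' every lying/sitting period qualifies. The median makes the baseline
#' robust to transient spikes during rest.
#'
#' @param hr An [hr_series].
#' @param labels A [label_track] on the same time base.
#' @return Resting heart rate in bpm (numeric scalar).
#' @export
resting_baseline <- function(hr, labels) {
  stopifnot(inherits(hr, "hr_series"), inherits(labels, "label_track"))
  iv <- labels$intervals
  walk <- iv$start_s[iv$activity == "walking"]
  cutoff <- if (length(walk)) min(walk) else Inf
  rest <- iv[iv$activity %in% c("lying", "sitting") & iv$end_s <= cutoff, ,
             drop = FALSE]
  if (nrow(rest) == 0L) stop("no pre-walking rest period")
  in_rest <- rep(FALSE, length(hr$t))
  for (i in seq_len(nrow(rest)))
    in_rest <- in_rest | (hr$t >= rest$start_s[i] & hr$t < rest$end_s[i])
  if (!any(in_rest)) stop("no pre-walking rest period")
  stats::median(hr$hr_bpm[in_rest])
}

#' Heart-rate deviation from a resting baseline
#'
#' @param hr An [hr_series] (or numeric vector of bpm values).
#' @param baseline Resting heart rate in bpm.
#' @return Numeric vector of deviations in bpm, `hr - baseline`.
#' @export
hr_deviation <- function(hr, baseline) {
  vals <- if (inherits(hr, "hr_series")) hr$hr_bpm else as.numeric(hr)
  vals - baseline
}

#' Correlate movement intensity with heart-rate deviation
#'
#' For every 5-s window whose truth label is walking or jogging (active
#' periods by label, not by cut-point prediction), the rolling-median
#' magnitude at the window end is paired with the heart-rate deviation at
#' the nearest heart-rate timestamp within 1 s. Pairs are pooled across
#' subjects and summarized by a Pearson correlation with the exact
#' t-based two-sided p-value.
#'
#' @param cohort List of subjects, each with `accel`, `labels` and `hr`.
#' @param window_s Window duration in seconds.
#' @param spec A [filter_spec].
#' @param minutes Truncation budget in minutes.
#' @return An object of class `vitals_result`: per-subject baselines, the
#'   pooled pair table (`subject_id`, `window_end_s`, `magnitude`,
#'   `hr_deviation`), Pearson `r`, `p`, pair count `n`, and the number of
#'   windows dropped for lack of a heart-rate match.
#' @export
correlate_vitals <- function(cohort, window_s = 5, spec = filter_spec(),
                             minutes = 20) {
  baselines <- numeric(0)
  pairs <- list()
  dropped <- 0L
  for (subj in cohort) {
    stopifnot(inherits(subj$hr, "hr_series"))
    base <- resting_baseline(subj$hr, subj$labels)
    baselines[subj$accel$subject_id] <- base
    tr <- truncate_last(subj$accel, subj$labels, minutes)
    filt <- bandpass(tr$recording, spec)
    med <- rolling_median(magnitude(filt), window_s)
    ws <- segment_windows(filt, tr$labels, window_s = window_s)
    act <- which(ws$label %in% c("walking", "jogging"))
    if (!length(act)) next
    vals <- window_magnitudes(ws, med)[act]
    ends <- ws$end_time_s[act]
    dev <- hr_deviation(subj$hr, base)
    nearest <- vapply(ends, function(tt) {
      i <- which.min(abs(subj$hr$t - tt))
      if (abs(subj$hr$t[i] - tt) <= 1) i else NA_integer_
    }, 1L)
    ok <- !is.na(nearest)
    dropped <- dropped + sum(!ok)
    if (any(ok))
      pairs[[length(pairs) + 1L]] <- data.frame(
        subject_id = subj$accel$subject_id, window_end_s = ends[ok],
        magnitude = vals[ok], hr_deviation = dev[nearest[ok]],
        stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("fewer than 3 magnitude/heart-rate pairs")
  ct <- stats::cor.test(pairs$magnitude, pairs$hr_deviation,
                        method = "pearson")
  structure(list(baselines = baselines, pairs = pairs,
                 r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
                 dropped = dropped),
            class = "vitals_result")
}

#' @export
print.vitals_result <- function(x, ...) {
  cat(sprintf(
    "<vitals_result> %d subjects, %d active-window pairs (%d dropped)\n",
    length(x$baselines), x$n, x$dropped))
  cat(sprintf("Pearson r = %.3f, p = %.3g\n", x$r, x$p))
  invisible(x)
}

#' @export
plot.vitals_result <- function(x, ...) {
  graphics::plot(x$pairs$magnitude, x$pairs$hr_deviation,
                 xlab = "rolling magnitude (g)",
                 ylab = "heart-rate deviation (bpm)",
                 main = sprintf("r = %.2f (n = %d)", x$r, x$n), ...)
  invisible(x)
}
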