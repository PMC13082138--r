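#' Prepare per-subject labeled windows for classification
#'
#' Standard preparation path for the multi-class classifier: truncate to
#' the last `minutes`, band-pass filter at the native rate, downsample to
#' `rate_hz`, and cut labeled windows (so `window_len = window_s *
#' rate_hz` in rate-sensitivity experiments).
#'
#' @param cohort List of subjects, each a list with elements `accel`
#'   ([accel_recording]) and `labels` ([label_track]) (a `hr` element is
#'   carried along untouched).
#' @param window_s Window duration in seconds.
#' @param rate_hz Target sampling rate in Hz.
#' @param spec A [filter_spec].
#' @param minutes Truncation budget in minutes.
#' @param stride_s Stride between window ends in seconds (default
#'   `window_s`, i.e. non-overlapping; a smaller stride yields
#'   overlapping windows, useful to hold the window count comparable
#'   across window sizes).
#' @return List of `window_set` objects, one per subject.
#' @export
prepare_cohort_windows <- function(cohort, window_s = 5, rate_hz = 50,
                                   spec = filter_spec(), minutes = 20,
                                   stride_s = window_s) {
  lapply(cohort, function(subj) {
    tr <- truncate_last(subj$accel, subj$labels, minutes)
    filt <- bandpass(tr$recording, spec)
    res <- resample_accel(filt, rate_hz)
    segment_windows(res, tr$labels, window_s = window_s,
                    stride_s = stride_s)
  })
}

pool_window_sets <- function(window_sets) {
  n_tot <- sum(vapply(window_sets, function(w) length(w$label), 1L))
  win_len <- window_sets[[1L]]$window_len
  samples <- array(NA_real_, dim = c(n_tot, win_len, 3L))
  labels <- character(n_tot)
  at <- 0L
  for (w in window_sets) {
    k <- length(w$label)
    if (k) {
      samples[at + seq_len(k), , ] <- w$samples
      labels[at + seq_len(k)] <- as.character(w$label)
      at <- at + k
    }
  }
  list(samples = samples, labels = factor(labels,
                                          levels = activity_classes()))
}

#' Leave-one-subject-out cross-validation of the CNN classifier
#'
#' One fold per subject: the held-out subject's windows appear in neither
#' the training set nor the standardization statistics of that fold. The
#' fold model is built and trained with seed `config$seed + fold index`.
#' Subjects with zero retained windows are skipped with a warning.
#'
#' @param cohort List of subjects as in [prepare_cohort_windows()], or a
#'   pre-computed list of `window_set` objects.
#' @param config A [cnn_config].
#' @param spec A [filter_spec] used when preparing windows.
#' @param minutes Truncation budget in minutes.
#' @param epochs Optional override of `config$epochs`.
#' @param stride_s Stride between window ends in seconds (default
#'   `window_s`).
#' @return An object of class `loocv_result`: per-fold results (held-out
#'   subject, true/predicted labels, probabilities, weighted metrics) and
#'   pooled weighted metrics over all folds.
#' @export
loocv <- function(cohort, config = cnn_config(), spec = filter_spec(),
                  minutes = 20, epochs = NULL,
                  stride_s = config$window_s) {
  window_sets <- if (length(cohort) && inherits(cohort[[1L]], "window_set"))
    cohort
  else
    prepare_cohort_windows(cohort, config$window_s, config$rate_hz, spec,
                           minutes, stride_s = stride_s)
  if (length(window_sets) < 3L) stop("LOOCV needs at least 3 subjects")
  counts <- vapply(window_sets, function(w) length(w$label), 1L)
  empty <- counts == 0L
  if (any(empty)) {
    warning("skipping subject(s) with zero retained windows: ",
            paste(vapply(window_sets[empty], `[[`, "", "subject_id"),
                  collapse = ", "))
    window_sets <- window_sets[!empty]
  }
  folds <- vector("list", length(window_sets))
  for (i in seq_along(window_sets)) {
    test_ws <- window_sets[[i]]
    train_pool <- pool_window_sets(window_sets[-i])
    fold_cfg <- config
    fold_cfg$seed <- config$seed + i
    model <- build_cnn(fold_cfg)
    model <- train_cnn(model, train_pool$samples, train_pool$labels,
                       epochs = epochs)
    pred <- predict(model, test_ws)
    folds[[i]] <- list(held_out_subject = test_ws$subject_id,
                       y_true = test_ws$label, y_pred = pred$labels,
                       probabilities = pred$probabilities,
                       metrics = weighted_metrics(test_ws$label,
                                                  pred$labels))
  }
  y_true <- factor(unlist(lapply(folds, function(f) as.character(f$y_true))),
                   levels = activity_classes())
  y_pred <- factor(unlist(lapply(folds, function(f) as.character(f$y_pred))),
                   levels = activity_classes())
  structure(list(folds = folds, y_true = y_true, y_pred = y_pred,
                 metrics = weighted_metrics(y_true, y_pred),
                 config = config),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<loocv_result> %d folds, %d windows (%g s @ %g Hz)\n",
    length(x$folds), length(x$y_true), x$config$window_s,
    x$config$rate_hz))
  cat(sprintf(
    "pooled weighted: accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f\n",
    m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

#' @export
summary.loocv_result <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(object$folds, function(f)
    data.frame(subject = f$held_out_subject, n = length(f$y_true),
               accuracy = f$metrics$accuracy, precision = f$metrics$precision,
               recall = f$metrics$recall, f1 = f$metrics$f1)))
  out <- list(per_fold = per_fold, pooled = object$metrics,
              per_class_f1 = per_class_f1(object$folds),
              confusion = confusion_counts(object$y_true, object$y_pred))
  class(out) <- "summary.loocv_result"
  out
}

#' @export
print.summary.loocv_result <- function(x, ...) {
  cat("Per-fold weighted metrics:\n")
  print(x$per_fold, row.names = FALSE, digits = 3)
  cat("\nPer-class F1 (pooled over folds):\n")
  print(round(x$per_class_f1, 3))
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
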