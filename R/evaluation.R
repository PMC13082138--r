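#' Support-weighted multi-class metrics
#'
#' Per-class precision, recall and F1 are averaged with weights
#' proportional to the true class supports `N_c / N`. With this
#' weighting, recall is algebraically identical to overall accuracy. A
#' class that is never predicted has undefined precision; it contributes
#' 0 to the weighted average, with a warning.
#'
#' @param y_true,y_pred Equal-length factors (or characters) over the
#'   five activity classes.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
weighted_metrics <- function(y_true, y_pred) {
  y_true <- as_activity_factor(y_true)
  y_pred <- as_activity_factor(y_pred)
  if (length(y_true) == 0L) stop("empty label vectors")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  cm <- confusion_counts(y_true, y_pred)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  present <- support > 0
  prec <- ifelse(predicted > 0, tp / pmax(predicted, 1L), NA_real_)
  rec <- ifelse(present, tp / pmax(support, 1L), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), 0)
  if (any(present & is.na(prec))) {
    warning("class(es) never predicted contribute precision 0: ",
            paste(names(support)[present & is.na(prec)], collapse = ", "))
    prec[present & is.na(prec)] <- 0
  }
  f1[present & is.na(f1)] <- 0
  w <- support[present] / sum(support)
  list(accuracy = sum(tp) / length(y_true),
       precision = sum(w * prec[present]),
       recall = sum(w * rec[present]),
       f1 = sum(w * f1[present]))
}

as_activity_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), activity_classes())
  if (length(bad))
    stop("not an activity label: ", paste(bad, collapse = ", "))
  factor(x, levels = activity_classes())
}

#' Five-class confusion matrix
#'
#' Rows are truth, columns are prediction, in the fixed class order.
#' The trace divided by the total count equals accuracy.
#'
#' @inheritParams weighted_metrics
#' @return A 5 x 5 integer matrix of counts.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as_activity_factor(y_true)
  y_pred <- as_activity_factor(y_pred)
  unclass(table(truth = y_true, prediction = y_pred))
}

#' Per-class F1 pooled across folds
#'
#' Pools all folds' true and predicted labels, then computes one F1 per
#' class from the pooled confusion matrix (micro-pooled per class, not
#' averaged over folds). Classes absent from the pooled truth get `NA`.
#'
#' @param folds A `loocv_result`, or a list of fold results each holding
#'   `y_true` and `y_pred`.
#' @return Named numeric vector of per-class F1 scores.
#' @export
per_class_f1 <- function(folds) {
  if (inherits(folds, "loocv_result")) folds <- folds$folds
  if (length(folds) == 0L) stop("need at least one fold")
  y_true <- unlist(lapply(folds, function(f) as.character(f$y_true)))
  y_pred <- unlist(lapply(folds, function(f) as.character(f$y_pred)))
  cm <- confusion_counts(y_true, y_pred)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  f1 <- vapply(seq_along(tp), function(i) {
    if (support[i] == 0L) return(NA_real_)
    prec <- if (predicted[i] > 0) tp[i] / predicted[i] else 0
    rec <- tp[i] / support[i]
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 1)
  stats::setNames(f1, rownames(cm))
}

#' Window-size and sampling-rate sensitivity grid
#'
#' Runs [loocv()] at every combination of window size and sampling rate
#' and emits one row per subject, combination and metric, with scores in
#' percent: the long-format table feeding [mixed_effects()]. A failed
#' cell is recorded as missing (with a warning), never fabricated.
#'
#' @param cohort List of subjects as in [prepare_cohort_windows()].
#' @param windows Numeric vector of window sizes in seconds.
#' @param rates Numeric vector of sampling rates in Hz.
#' @param config Base [cnn_config]; its `window_s`/`rate_hz` are
#'   overridden per cell, everything else (seed included) is shared, so
#'   any one cell reproduces the standalone [loocv()] run with the same
#'   settings.
#' @param spec A [filter_spec].
#' @param minutes Truncation budget in minutes.
#' @param epochs Optional override of `config$epochs`.
#' @return A `metric_table` data frame with columns `subject_id`,
#'   `window_s`, `rate_hz`, `metric`, `score` (percent).
#' @export
sensitivity_grid <- function(cohort, windows = c(1, 2, 4, 5, 8, 12),
                             rates = c(5, 10, 25, 50),
                             config = cnn_config(), spec = filter_spec(),
                             minutes = 20, epochs = NULL) {
  rows <- list()
  for (w in windows) for (r in rates) {
    cell <- tryCatch({
      cfg <- cnn_config(window_s = w, rate_hz = r,
                        conv_blocks = config$conv_blocks,
                        dense_units = config$dense_units,
                        dropout = config$dropout, epochs = config$epochs,
                        batch_size = config$batch_size,
                        learning_rate = config$learning_rate,
                        seed = config$seed)
      loocv(cohort, cfg, spec, minutes, epochs = epochs)
    }, error = function(e) {
      warning(sprintf("grid cell (%g s, %g Hz) failed: %s", w, r,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(cell)) next
    for (f in cell$folds) {
      m <- f$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = f$held_out_subject, window_s = w, rate_hz = r,
        metric = c("accuracy", "precision", "recall", "f1"),
        score = 100 * c(m$accuracy, m$precision, m$recall, m$f1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)  # every cell failed
  class(out) <- c("metric_table", class(out))
  out
}

#' Mean-score heatmap of a sensitivity grid
#'
#' Averages one metric over subjects for each window x rate cell and
#' draws an image plot (numbers stay in the `metric_table`; the plot is
#' a side artifact).
#'
#' @param metric_table Output of [sensitivity_grid()].
#' @param metric Which metric to draw.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the matrix of cell means (windows x rates).
#' @export
plot_metric_heatmap <- function(metric_table, metric = "f1", ...) {
  sub <- metric_table[metric_table$metric == metric, , drop = FALSE]
  agg <- stats::aggregate(score ~ window_s + rate_hz, data = sub, FUN = mean)
  ws <- sort(unique(agg$window_s)); rs <- sort(unique(agg$rate_hz))
  mat <- matrix(NA_real_, length(ws), length(rs),
                dimnames = list(paste0(ws, "s"), paste0(rs, "Hz")))
  mat[cbind(match(agg$window_s, ws), match(agg$rate_hz, rs))] <- agg$score
  graphics::image(seq_along(ws), seq_along(rs), mat, axes = FALSE,
                  xlab = "window size", ylab = "sampling rate",
                  main = paste("mean", metric, "(%)"), ...)
  graphics::axis(1, seq_along(ws), rownames(mat))
  graphics::axis(2, seq_along(rs), colnames(mat))
  for (i in seq_along(ws)) for (j in seq_along(rs))
    graphics::text(i, j, sprintf("%.1f", mat[i, j]))
  invisible(mat)
}

#' Sensitivity of CNN performance to the filter's high-frequency cutoff
#'
#' Re-runs the CNN LOOCV with the band-pass high cutoff set to each value
#' in `high_cuts` (the low cutoff and everything else unchanged) and
#' reports the pooled weighted metrics per cutoff. The first row with the
#' default 2 Hz cutoff reproduces the baseline run.
#'
#' @param cohort List of subjects as in [prepare_cohort_windows()].
#' @param high_cuts High-frequency cutoffs in Hz; all must be below the
#'   native Nyquist frequency.
#' @param config A [cnn_config].
#' @param spec Base [filter_spec] supplying the low cutoff, order, mode.
#' @param minutes Truncation budget in minutes.
#' @param epochs Optional override of `config$epochs`.
#' @return Data frame with one row per cutoff: `high_hz`, `accuracy`,
#'   `precision`, `recall`, `f1` (pooled weighted, in \\[0, 1\\]).
#' @export
cutoff_sensitivity <- function(cohort, high_cuts = c(2, 5, 10, 15, 20),
                               config = cnn_config(), spec = filter_spec(),
                               minutes = 20, epochs = NULL) {
  nyq <- min(vapply(cohort, function(s) s$accel$sampling_rate_hz / 2, 1))
  if (any(high_cuts >= nyq))
    stop("high cutoff at or above the Nyquist frequency (", nyq, " Hz)")
  rows <- lapply(high_cuts, function(hc) {
    sp <- filter_spec(low_hz = spec$low_hz, high_hz = hc,
                      order = spec$order, mode = spec$mode)
    res <- loocv(cohort, config, sp, minutes, epochs = epochs)
    data.frame(high_hz = hc, accuracy = res$metrics$accuracy,
               precision = res$metrics$precision,
               recall = res$metrics$recall, f1 = res$metrics$f1)
  })
  do.call(rbind, rows)
}
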