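# Brute-force reference implementations, independent of the package's
# code paths. These stay deliberately naive: per-window sort-and-middle
# medians, explicit confusion-count arithmetic.

bf_rolling_median <- function(x, n_win) {
  n <- length(x)
  left <- (n_win - 1L) %/% 2L
  right <- n_win - 1L - left
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - left)
    hi <- min(n, i + right)
    w <- sort(x[lo:hi])
    m <- length(w)
    if (m %% 2L == 1L) w[(m + 1L) %/% 2L]
    else mean(w[c(m %/% 2L, m %/% 2L + 1L)])
  }, 1)
}

bf_rolling_mad <- function(x, n_win) {
  n <- length(x)
  left <- (n_win - 1L) %/% 2L
  right <- n_win - 1L - left
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - left):min(n, i + right)]
    mean(abs(w - mean(w)))
  }, 1)
}

bf_confusion <- function(y_true, y_pred, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  cm
}

bf_weighted_metrics <- function(y_true, y_pred, classes) {
  cm <- bf_confusion(y_true, y_pred, classes)
  acc <- sum(diag(cm)) / length(y_true)
  prec <- rec <- f1 <- 0
  for (cl in classes) {
    support <- sum(cm[cl, ])
    if (support == 0) next
    w <- support / length(y_true)
    p <- if (sum(cm[, cl]) > 0) cm[cl, cl] / sum(cm[, cl]) else 0
    r <- cm[cl, cl] / support
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    prec <- prec + w * p
    rec <- rec + w * r
    f1 <- f1 + w * f
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

bf_per_class_f1 <- function(y_true, y_pred, classes) {
  cm <- bf_confusion(y_true, y_pred, classes)
  sapply(classes, function(cl) {
    support <- sum(cm[cl, ])
    if (support == 0) return(NA_real_)
    p <- if (sum(cm[, cl]) > 0) cm[cl, cl] / sum(cm[, cl]) else 0
    r <- cm[cl, cl] / support
    if (p + r > 0) 2 * p * r / (p + r) else 0
  })
}

bf_calibrate <- function(values, active, step = 0.001) {
  grid <- seq(min(values), max(values), by = step)
  miss <- vapply(grid, function(th)
    sum(!active & values > th) + sum(active & values <= th), 1)
  i <- which.min(miss)
  list(threshold = grid[i], overlap_count = miss[i])
}

random_labels <- function(n, classes, seed) {
  set.seed(seed)
  list(y_true = sample(classes, n, replace = TRUE),
       y_pred = sample(classes, n, replace = TRUE))
}
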