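test_that("weighted metrics agree with the brute-force oracle", {
  classes <- activity_classes()
  for (i in 1:40) {
    rl <- random_labels(sample(5:60, 1), sample(classes, 3), seed = 100 + i)
    m <- suppressWarnings(weighted_metrics(rl$y_true, rl$y_pred))
    bf <- bf_weighted_metrics(rl$y_true, rl$y_pred, classes)
    expect_equal(m, bf, tolerance = 1e-12)
  }
  perfect <- rep(classes, 4)
  expect_equal(weighted_metrics(perfect, perfect),
               list(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_error(weighted_metrics(character(0), character(0)), "empty")
})

test_that("weighted recall equals accuracy on every instance", {
  classes <- activity_classes()
  for (i in 1:40) {
    rl <- random_labels(sample(5:80, 1),
                        sample(classes, sample(2:5, 1)), seed = 300 + i)
    m <- suppressWarnings(weighted_metrics(rl$y_true, rl$y_pred))
    expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
    cm <- confusion_counts(rl$y_true, rl$y_pred)
    expect_equal(sum(diag(cm)) / sum(cm), m$accuracy)
  }
})

test_that("confusion matrix has class supports as row sums", {
  rl <- random_labels(60, activity_classes(), seed = 12)
  cm <- confusion_counts(rl$y_true, rl$y_pred)
  supports <- table(factor(rl$y_true, levels = activity_classes()))
  expect_equal(unname(rowSums(cm)), as.vector(supports))
  expect_equal(sum(cm), 60)
  all_sit <- rep("sitting", 10)
  cm1 <- confusion_counts(rl$y_true[1:10], all_sit)
  expect_equal(sum(cm1[, "sitting"]), 10)
  expect_equal(sum(cm1[, setdiff(colnames(cm1), "sitting")]), 0)
})

test_that("per-class F1 pools folds rather than averaging them", {
  f1 <- list(y_true = c("lying", "lying", "walking"),
             y_pred = c("lying", "walking", "walking"))
  f2 <- list(y_true = c("lying", "walking", "walking"),
             y_pred = c("lying", "walking", "lying"))
  single <- per_class_f1(list(f1))
  expect_equal(unname(single["lying"]),
               unname(bf_per_class_f1(f1$y_true, f1$y_pred,
                                      activity_classes())["lying"]))
  pooled <- per_class_f1(list(f1, f2))
  bf <- bf_per_class_f1(c(f1$y_true, f2$y_true), c(f1$y_pred, f2$y_pred),
                        activity_classes())
  expect_equal(pooled, bf)
  expect_true(is.na(pooled[["jogging"]]))  # absent from pooled truth

  perfect <- list(y_true = activity_classes(), y_pred = activity_classes())
  expect_equal(unname(per_class_f1(list(perfect))), rep(1, 5))
})

test_that("metric table simulation has the declared cardinality", {
  tab <- simulate_metric_table(n_subjects = 4, seed = 2)
  expect_equal(nrow(tab), 4 * 6 * 4 * 4)
  expect_equal(sum(duplicated(tab[, 1:4])), 0)
})

test_that("mixed model recovers simulated fixed effects", {
  tab <- simulate_metric_table(
    n_subjects = 8,
    window_effects = c("1" = -10, "5" = -3, "12" = 0),
    rate_effects = c("5" = -8, "50" = 0),
    subject_sd = 8, resid_sd = 4, seed = 31)
  fit <- mixed_effects(tab)
  cf <- fit$coefficients
  w1 <- cf[cf$term == "window 1 s vs. 12 s", ]
  expect_lt(w1$ci_lo, -10); expect_gt(w1$ci_hi, -10)
  r5 <- cf[cf$term == "rate 5 Hz vs. 50 Hz", ]
  expect_lt(r5$ci_lo, -8); expect_gt(r5$ci_hi, -8)
  expect_equal(w1$ci_hi - w1$beta, 1.96 * w1$se, tolerance = 1e-9)
  expect_gt(fit$group_var, 0)
  expect_error(mixed_effects(tab[tab$subject_id %in%
                                   unique(tab$subject_id)[1:2], ]),
               "at least 3 subjects")
})

test_that("identical accuracy and recall columns give identical contrasts", {
  # with weighted recall == accuracy the two metric contrasts coincide
  tab <- simulate_metric_table(
    n_subjects = 6,
    metric_effects = c(accuracy = -3.3, precision = 8.3, recall = 0,
                       f1 = 0), seed = 9)
  # overwrite recall scores with the accuracy scores cell by cell
  acc <- tab$metric == "accuracy"
  rec <- tab$metric == "recall"
  key <- function(d) paste(d$subject_id, d$window_s, d$rate_hz)
  tab$score[rec] <- tab$score[acc][match(key(tab[rec, ]),
                                         key(tab[acc, ]))]
  fit <- mixed_effects(tab)
  cf <- fit$coefficients
  expect_equal(cf[cf$term == "accuracy vs. f1", "beta"],
               cf[cf$term == "recall vs. f1", "beta"], tolerance = 1e-9)
})

test_that("null simulations keep z statistics near the reference level", {
  hits <- 0L; total <- 0L
  for (i in 1:20) {
    tab <- simulate_metric_table(
      n_subjects = 6,
      window_effects = c("1" = 0, "12" = 0),
      rate_effects = c("5" = 0, "50" = 0),
      metric_effects = c(f1 = 0, accuracy = 0),
      subject_sd = 5, resid_sd = 5, seed = 700 + i)
    cf <- mixed_effects(tab)$coefficients
    zs <- cf$z[cf$term != "(Intercept)"]
    hits <- hits + sum(abs(zs) < 1.96)
    total <- total + length(zs)
  }
  expect_gte(hits / total, 0.85)  # nominal 95% minus Monte-Carlo slack
})

test_that("sensitivity grid emits one row per subject, cell and metric", {
  cohort <- small_cohort(4, seed = 11)
  tab <- suppressWarnings(
    sensitivity_grid(cohort, windows = c(2, 5), rates = c(25, 50),
                     config = cnn_config(seed = 2), epochs = 2))
  expect_s3_class(tab, "metric_table")
  expect_equal(nrow(tab), 2 * 2 * 4 * 4)
  expect_true(all(tab$score >= 0 & tab$score <= 100))
  # a failing cell is dropped, not fabricated: 1 s at 5 Hz is too short
  tab2 <- suppressWarnings(
    sensitivity_grid(cohort, windows = c(1), rates = c(5),
                     config = cnn_config(seed = 2), epochs = 2))
  expect_null(tab2)
})

test_that("grid cells reproduce the standalone LOOCV run", {
  cohort <- small_cohort(4, seed = 11)
  ws <- prepare_cohort_windows(cohort, 5, 50)
  base <- suppressWarnings(loocv(ws, cnn_config(seed = 2), epochs = 2))
  tab <- suppressWarnings(
    sensitivity_grid(cohort, windows = 5, rates = 50,
                     config = cnn_config(seed = 2), epochs = 2))
  f1_grid <- tab$score[tab$metric == "f1"]
  f1_base <- 100 * vapply(base$folds, function(f) f$metrics$f1, 1)
  expect_equal(sort(f1_grid), sort(f1_base), tolerance = 1e-9)
})
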