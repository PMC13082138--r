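test_that("thresholding is strict and monotone", {
  s0 <- mag_series(rep(0, 100))
  expect_true(all(classify_activity_level(s0)$state == "inactive"))

  s1 <- mag_series(rep(0.10, 100))
  expect_true(all(classify_activity_level(s1)$state == "active"))

  s_tie <- mag_series(rep(0.07, 100))
  expect_true(all(classify_activity_level(s_tie)$state == "inactive"))

  set.seed(3)
  s <- mag_series(runif(300, 0, 0.2))
  lo <- classify_activity_level(s, cutpoint_config(threshold_g = 0.05))
  hi <- classify_activity_level(s, cutpoint_config(threshold_g = 0.09))
  # raising the threshold never converts inactive to active
  expect_false(any(lo$state == "inactive" & hi$state == "active"))
})

test_that("classification at a sample depends only on its window", {
  set.seed(4)
  fs <- 50
  x <- runif(600, 0, 0.2)
  n_win <- round(5 * fs)
  half <- (n_win - 1) %/% 2
  i <- 300
  x2 <- x
  x2[seq_len(i - half - 1)] <- 5       # far past
  x2[(i + (n_win - 1 - half) + 1):600] <- 5  # far future
  m1 <- rolling_median(mag_series(x, fs), 5)$m[i]
  m2 <- rolling_median(mag_series(x2, fs), 5)$m[i]
  expect_identical(m1, m2)
})

test_that("rolling MAD matches closed forms and the brute-force oracle", {
  const <- mag_series(rep(0.5, 200))
  expect_equal(rolling_mad(const, 5)$m, rep(0, 200))

  # alternating a, b: every full window holds them equally
  ab <- mag_series(rep(c(0.2, 0.6), 100), fs = 2)
  out <- rolling_mad(ab, 5)$m  # 10-sample windows
  interior <- out[10:190]
  expect_equal(interior, rep(abs(0.2 - 0.6) / 2, length(interior)))

  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:300, 1)
    n_win <- sample(3:15, 1)
    x <- runif(n)
    expect_equal(rolling_mad(mag_series(x, fs = 1), n_win)$m,
                 bf_rolling_mad(x, n_win), tolerance = 1e-12)
  }
})

test_that("calibration recovers a separating threshold", {
  set.seed(5)
  vals <- c(runif(40, 0, 0.02), runif(60, 0.2, 0.4))
  labs <- rep(c("sitting", "walking"), c(40, 60))
  cal <- calibrate_threshold(vals, labs)
  expect_equal(cal$overlap_count, 0L)
  expect_gt(cal$threshold, 0.02)
  expect_lte(cal$threshold, 0.2)

  expect_error(calibrate_threshold(runif(10), rep("sitting", 10)),
               "single class")
})

test_that("calibration equals brute-force grid enumeration", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    active <- runif(n) < 0.4
    # overlapping distributions force a nontrivial minimum
    vals <- ifelse(active, rnorm(n, 0.12, 0.05), rnorm(n, 0.04, 0.03))
    vals <- pmax(vals, 0)
    labs <- ifelse(active, "walking", "standing")
    cal <- calibrate_threshold(vals, labs)
    bf <- bf_calibrate(vals, active)
    expect_equal(cal$overlap_count, as.integer(bf$overlap_count))
    expect_equal(cal$threshold, bf$threshold)
  }
})

test_that("identical class distributions give min-class-size overlap", {
  vals <- rep(seq(0.01, 0.1, length.out = 20), 2)
  labs <- rep(c("sitting", "walking"), each = 20)
  cal <- calibrate_threshold(vals, labs)
  expect_equal(cal$overlap_count, 20L)
  expect_equal(cal$threshold, min(vals))  # tie broken toward the smallest
})

test_that("binary metrics follow the confusion-matrix arithmetic", {
  p <- factor(rep(c("active", "inactive"), c(12, 8)),
              levels = c("inactive", "active"))
  expect_equal(evaluate_binary(p, p),
               list(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP=9, FP=3, FN=1, TN=7
  truth <- rep(c("active", "inactive", "active", "inactive"),
               c(9, 3, 1, 7))
  pred <- rep(c("active", "active", "inactive", "inactive"),
              c(9, 3, 1, 7))
  m <- evaluate_binary(pred, truth)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.9)
  expect_equal(m$accuracy, 0.8)

  # nothing predicted active: precision reported as 0, f1 = 0
  m0 <- evaluate_binary(rep("inactive", 10),
                        rep(c("active", "inactive"), 5))
  expect_equal(m0$precision, 0)
  expect_equal(m0$recall, 0)
  expect_equal(m0$f1, 0)

  expect_error(evaluate_binary(rep("active", 3), rep("active", 4)),
               "same length")
})

test_that("f1 stays within [0, 1] and vanishes with precision or recall", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    pred <- sample(c("active", "inactive"), n, replace = TRUE)
    truth <- sample(c("active", "inactive"), n, replace = TRUE)
    m <- evaluate_binary(pred, truth)
    expect_gte(m$f1, 0)
    expect_lte(m$f1, 1)
    if (m$precision == 0 || m$recall == 0) expect_equal(m$f1, 0)
  }
})

test_that("subject split keeps participants disjoint and is seeded", {
  ids <- sprintf("s%02d", 1:10)
  sp1 <- subject_split(ids, 0.8, seed = 4)
  sp2 <- subject_split(ids, 0.8, seed = 4)
  expect_identical(sp1, sp2)
  expect_length(sp1$train, 8)
  expect_length(intersect(sp1$train, sp1$test), 0)
  expect_setequal(c(sp1$train, sp1$test), ids)
})

test_that("the MAD cut-point runs through the window pipeline", {
  subj <- small_cohort(4, seed = 11)[[1]]
  tab <- cutpoint_windows(subj$accel, subj$labels,
                          cutpoint_config(metric = "mad"))
  expect_true(all(tab$value >= 0))
  expect_true(all(levels(tab$pred) == c("inactive", "active")))
})
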