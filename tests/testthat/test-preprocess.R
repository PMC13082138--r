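test_that("band-pass keeps the passband, rejects stopband and DC", {
  rec1 <- sine_recording(1)
  out <- bandpass(rec1, filter_spec())
  expect_gt(steady_amp(out$x), 0.95)
  expect_lt(steady_amp(out$x), 1.05)

  rec10 <- sine_recording(10)
  out10 <- bandpass(rec10, filter_spec())
  expect_lt(steady_amp(out10$x), 10^(-20 / 20))  # >= 20 dB down

  t <- seq(0, 120, by = 0.02)
  dc <- accel_recording("dc", t, rep(0.7, length(t)), rep(-1, length(t)),
                        rep(0, length(t)), sampling_rate_hz = 50)
  outdc <- bandpass(dc, filter_spec())
  expect_lt(abs(mean(outdc$x)), 0.01)
  expect_lt(abs(mean(outdc$y)), 0.01)

  expect_error(bandpass(rec1, filter_spec(high_hz = 30)), "Nyquist")
})

test_that("single-pass Butterworth gain at each cutoff is -3 dB within 2%", {
  spec <- filter_spec(mode = "causal")
  for (f0 in c(0.05, 2)) {
    rec <- sine_recording(f0, dur_s = if (f0 < 0.5) 2000 else 300)
    out <- bandpass(rec, spec)
    n <- length(out$x)
    gain <- sd(out$x[(n %/% 2):n]) / sd(rec$x[(n %/% 2):n])
    expect_equal(gain, 1 / sqrt(2), tolerance = 0.02)
  }
})

test_that("magnitude is the Euclidean norm and rotation invariant", {
  t <- c(0, 0.02)
  rec <- accel_recording("m", t, c(3, 0), c(4, 0), c(0, 0),
                         sampling_rate_hz = 50)
  expect_equal(magnitude(rec)$m, c(5, 0))

  set.seed(42)
  for (i in 1:10) {
    n <- 50
    tt <- (seq_len(n) - 1) / 50
    xyz <- matrix(rnorm(3 * n), n, 3)
    rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    r1 <- accel_recording("r", tt, xyz[, 1], xyz[, 2], xyz[, 3],
                          sampling_rate_hz = 50)
    v <- xyz %*% rot
    r2 <- accel_recording("r", tt, v[, 1], v[, 2], v[, 3],
                          sampling_rate_hz = 50)
    expect_equal(magnitude(r1)$m, magnitude(r2)$m, tolerance = 1e-9)
  }
})

test_that("rolling median matches the brute-force oracle exactly", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(10:1000, 1)
    n_win <- sample(3:25, 1)
    x <- rnorm(n)
    s <- mag_series(x, fs = 1)
    expect_identical(rolling_median(s, window_s = n_win)$m,
                     bf_rolling_median(x, n_win))
  }
  expect_error(rolling_median(mag_series(rnorm(10), fs = 1), 2),
               "at least 3 samples")
})

test_that("rolling median is constant-preserving and spike-robust", {
  s <- mag_series(rep(0.3, 400))
  expect_equal(rolling_median(s, 5)$m, rep(0.3, 400))

  set.seed(1)
  x <- runif(500, 0.1, 0.2)
  xs <- x
  spike_at <- sample(100:400, 20)  # 20 spikes << N/2 = 125
  xs[spike_at] <- 50
  out <- rolling_median(mag_series(xs), 5)$m
  expect_true(all(out >= 0.1 & out <= 0.2))
})

test_that("the centered 5-s window at 50 Hz implies a 2.5-s causal delay", {
  n_win <- round(5 * 50)
  expect_equal(n_win, 250)
  delay_samples <- (n_win - 1) / 2
  expect_equal(delay_samples, 124.5)
  expect_equal(delay_samples / 50, 2.49, tolerance = 1e-9)
})

test_that("truncation keeps the last 20 minutes and clips labels", {
  fs <- 50
  t <- seq(0, 30 * 60, by = 1 / fs)
  rec <- accel_recording("tr", t, rnorm(length(t), 0, 0.01),
                         rnorm(length(t), 0, 0.01),
                         rnorm(length(t), 0, 0.01), sampling_rate_hz = fs)
  lab <- label_track("tr", c(0, 500, 1200), c(500, 1200, 1800),
                     c("sitting", "walking", "sitting"))
  out <- truncate_last(rec, lab)
  expect_equal(max(out$recording$t), max(rec$t))
  expect_equal(max(rec$t) - min(out$recording$t), 20 * 60,
               tolerance = 1 / fs)
  # boundary-spanning interval clipped to start at the cut
  expect_equal(out$labels$intervals$start_s[1], 30 * 60 - 20 * 60)

  short <- small_cohort(3, seed = 21)[[1]]
  kept <- truncate_last(short$accel, short$labels)
  expect_identical(kept$recording$t, short$accel$t)
})

test_that("downsampling preserves in-band content and removes aliases", {
  rec <- sine_recording(1, dur_s = 200)
  same <- resample_accel(rec, 50)
  expect_identical(same$x, rec$x)

  half <- resample_accel(rec, 25)
  expect_equal(half$sampling_rate_hz, 25)
  expect_equal(length(half$t), ceiling(length(rec$t) / 2))
  expect_equal(steady_amp(half$x), 1, tolerance = 0.02)

  rec3 <- sine_recording(3, dur_s = 200)
  low <- resample_accel(rec3, 5)
  expect_lt(steady_amp(low$x), 0.1)  # >= 10x attenuation above new Nyquist

  expect_error(resample_accel(rec, 15), "integer multiple")
})

test_that("windows are labeled by the most recent activity", {
  fs <- 50
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mk <- function(labels) {
    rec <- accel_recording("w", t, rnorm(length(t), 0, 0.01),
                           rnorm(length(t), 0, 0.01),
                           rnorm(length(t), 0, 0.01), sampling_rate_hz = fs)
    segment_windows(rec, labels, window_s = 5)
  }
  ws <- mk(constant_labels("w", 60, "sitting"))
  expect_length(ws$label, 12)
  expect_true(all(ws$label == "sitting"))

  # no transition interval: the final sample's interval wins
  ws2 <- mk(label_track("w", c(0, 32.5), c(32.5, 60),
                        c("sitting", "walking")))
  lab_by_end <- setNames(as.character(ws2$label), ws2$end_time_s)
  expect_equal(unname(lab_by_end[abs(as.numeric(names(lab_by_end)) - 34.98)
                                 < 0.01]), "walking")

  # transition overlap excludes the window
  ws3 <- mk(label_track("w", c(0, 30, 33), c(30, 33, 60),
                        c("sitting", "transition", "walking")))
  expect_gte(ws3$excluded_counts[["transition"]], 1L)
  expect_false(any(is.na(ws3$label)))
})

test_that("retained plus excluded windows account for every window", {
  cohort <- small_cohort(4, seed = 11)
  for (subj in cohort[1:2]) {
    filt <- bandpass(subj$accel)
    ws <- segment_windows(filt, subj$labels, window_s = 5)
    total <- floor((length(filt$t) - ws$window_len) /
                     (ws$window_len)) + 1
    expect_equal(length(ws$label) + sum(ws$excluded_counts), total)
    expect_true(all(as.character(ws$label) %in% activity_classes()))
  }
})

test_that("window length tracks the resampled rate", {
  cohort <- small_cohort(4, seed = 11)
  subj <- cohort[[1]]
  for (r in c(5, 10, 25)) {
    res <- resample_accel(bandpass(subj$accel), r)
    ws <- segment_windows(res, subj$labels, window_s = 5)
    expect_equal(ws$window_len, round(5 * r))
    expect_equal(dim(ws$samples)[2], round(5 * r))
  }
})

test_that("a window longer than the recording yields an empty set", {
  t <- seq(0, 3, by = 0.02)
  rec <- accel_recording("s", t, rnorm(length(t)), rnorm(length(t)),
                         rnorm(length(t)), sampling_rate_hz = 50)
  expect_warning(ws <- segment_windows(rec, constant_labels("s", 3), 5),
                 "longer than recording")
  expect_length(ws$label, 0)
})
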