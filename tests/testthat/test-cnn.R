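toy_windows <- function(n = 200, L = 100, fs = 50, seed = 5,
                        classes = c("sitting", "walking"),
                        freqs = c(0.3, 1.8)) {
  set.seed(seed)
  X <- array(0, c(n, L, 3))
  y <- rep(classes, length.out = n)
  tt <- seq_len(L) / fs
  for (i in seq_len(n)) {
    f <- freqs[match(y[i], classes)]
    ph <- runif(1, 0, 2 * pi)
    X[i, , 1] <- 0.1 * sin(2 * pi * f * tt + ph) + rnorm(L, 0, 0.02)
    X[i, , 2] <- 0.3 * sin(2 * pi * f * tt + ph) + rnorm(L, 0, 0.02)
    X[i, , 3] <- rnorm(L, 0, 0.02)
  }
  list(X = X, y = factor(y, levels = activity_classes()))
}

test_that("class weights are inverse-frequency with constant weight*count", {
  w <- class_weights(factor(rep(c("a", "b", "c", "d"), 25),
                            levels = c("a", "b", "c", "d")))
  expect_equal(unname(w), rep(1, 4))

  w2 <- class_weights(factor(rep(c("a", "b"), c(90, 10)),
                             levels = c("a", "b")))
  expect_equal(unname(w2), c(100 / (2 * 90), 100 / (2 * 10)))

  set.seed(2)
  counts <- c(lying = 5, sitting = 40, standing = 17, walking = 25,
              jogging = 3)
  labs <- factor(rep(names(counts), counts), levels = names(counts))
  w3 <- class_weights(labs)
  prods <- w3 * counts
  expect_equal(max(prods) - min(prods), 0, tolerance = 1e-12)

  expect_message(w4 <- class_weights(rep("sitting", 10)), "weight 0")
  expect_equal(unname(w4["lying"]), 0)
  expect_error(class_weights(character(0)), "empty")
})

test_that("model construction is shape-correct and seed-deterministic", {
  cfg <- cnn_config()
  m <- build_cnn(cfg)
  expect_equal(m$arch$input_len, 250)
  expect_equal(m$arch$n_classes, 5)
  m2 <- build_cnn(cfg)
  expect_identical(m$params, m2$params)
  m3 <- build_cnn(cnn_config(seed = 2))
  expect_false(identical(m$params, m3$params))

  expect_error(cnn_config(window_s = 1, rate_hz = 5), "at least 8")
  # short-but-valid windows get a clamped conv stack
  short <- build_cnn(cnn_config(window_s = 2, rate_hz = 5))
  expect_gte(short$arch$gap_len, 1)
})

test_that("untrained forward pass emits a probability simplex", {
  m <- build_cnn(cnn_config(window_s = 2, rate_hz = 50))
  set.seed(1)
  X <- array(rnorm(6 * 100 * 3), c(6, 100, 3))
  fw <- actipatch:::cnn_forward(m$arch, m$params, X)
  expect_equal(unname(rowSums(fw$probs)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(fw$probs >= 0))
})

test_that("training separates a two-class toy problem", {
  toy <- toy_windows()
  cfg <- cnn_config(window_s = 2, rate_hz = 50, epochs = 10, seed = 3)
  m <- suppressMessages(train_cnn(build_cnn(cfg), toy$X, toy$y))
  expect_true(all(is.finite(m$loss_history)))
  pred <- predict(m, toy$X)
  expect_gte(mean(pred$labels == toy$y), 0.95)
  expect_equal(rowSums(pred$probabilities), rep(1, nrow(toy$X)),
               tolerance = 1e-9)
  # argmax consistency with the fixed class order
  expect_equal(as.character(pred$labels),
               activity_classes()[max.col(pred$probabilities,
                                          ties.method = "first")])
})

test_that("training is reproducible and rejects degenerate input", {
  toy <- toy_windows(n = 60)
  cfg <- cnn_config(window_s = 2, rate_hz = 50, epochs = 3, seed = 8)
  m1 <- suppressMessages(train_cnn(build_cnn(cfg), toy$X, toy$y))
  m2 <- suppressMessages(train_cnn(build_cnn(cfg), toy$X, toy$y))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_history, m2$loss_history)

  one_class <- factor(rep("sitting", 60), levels = activity_classes())
  expect_error(suppressMessages(
    train_cnn(build_cnn(cfg), toy$X, one_class)), "single-class")
  expect_error(predict(build_cnn(cfg), toy$X), "not been trained")
  expect_error(predict(m1, array(0, c(2, 37, 3))), "must be n x")
})

test_that("standardization uses training statistics only", {
  toy <- toy_windows(n = 80)
  cfg <- cnn_config(window_s = 2, rate_hz = 50, epochs = 2, seed = 8)
  m <- suppressMessages(train_cnn(build_cnn(cfg), toy$X, toy$y))
  expect_length(m$norm$mean, 3)
  # predictions on shifted data use the stored statistics, so the
  # probabilities must differ from those on the original data
  shifted <- toy$X + 5
  p1 <- predict(m, toy$X)$probabilities
  p2 <- predict(m, shifted)$probabilities
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("LOOCV folds partition subjects without leakage", {
  cohort <- small_cohort(4, seed = 11)
  ws <- prepare_cohort_windows(cohort)
  res <- suppressWarnings(
    loocv(ws, cnn_config(epochs = 3, seed = 1)))
  expect_length(res$folds, 4)
  held <- vapply(res$folds, `[[`, "", "held_out_subject")
  expect_setequal(held, vapply(cohort, function(s) s$accel$subject_id, ""))
  # union of test windows = all windows, pairwise disjoint by subject
  expect_equal(length(res$y_true),
               sum(vapply(ws, function(w) length(w$label), 1L)))
  # per-window fingerprints: no test window appears in the fold's
  # training windows
  fingerprint <- function(wset) apply(wset$samples, 1, function(w)
    paste(signif(w[1:12], 10), collapse = "|"))
  keys <- lapply(ws, fingerprint)
  for (i in seq_along(ws)) {
    train_keys <- unlist(keys[-i])
    expect_length(intersect(keys[[i]], train_keys), 0)
  }
  # probabilities are a simplex and argmax equals the prediction
  for (f in res$folds) {
    expect_equal(rowSums(f$probabilities),
                 rep(1, nrow(f$probabilities)), tolerance = 1e-6)
    expect_equal(as.character(f$y_pred),
                 activity_classes()[max.col(f$probabilities,
                                            ties.method = "first")])
  }
})
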