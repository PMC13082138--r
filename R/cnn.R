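#' Configuration of the 1-D convolutional activity classifier
#'
#' The reference architecture stacks 1-D convolution blocks
#' (convolution, ReLU, optional max-pool), global average pooling over
#' time, one dense hidden layer with dropout, and a 5-way softmax output.
#' All sizes are config-driven so published variants can be dialed in.
#' For short inputs, kernels are clamped to the available temporal length
#' and pools are skipped, so any window with at least 8 samples is valid.
#'
#' @param window_s Window duration in seconds (default 5).
#' @param rate_hz Sampling rate of the windows in Hz (default 50).
#' @param conv_blocks List of `c(filters, kernel, pool)` triples; `pool = 0`
#'   disables pooling for that block.
#' @param dense_units Width of the dense hidden layer.
#' @param dropout Dropout rate applied after the dense hidden layer
#'   during training.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(window_s = 5, rate_hz = 50,
                       conv_blocks = list(c(32, 7, 2), c(64, 5, 2),
                                          c(64, 3, 0)),
                       dense_units = 64, dropout = 0.3, epochs = 30,
                       batch_size = 64, learning_rate = 1e-3, seed = 1L) {
  stopifnot(window_s > 0, rate_hz > 0, dense_units >= 1, epochs >= 1,
            batch_size >= 1, learning_rate > 0, dropout >= 0, dropout < 1)
  win_len <- round(window_s * rate_hz)
  if (win_len < 8)
    stop("window_s x rate_hz gives only ", win_len,
         " samples; at least 8 are required for the conv stack ",
         "(use a longer window or higher rate)")
  for (bl in conv_blocks)
    if (length(bl) != 3L || any(bl[1:2] < 1) || bl[3] < 0)
      stop("each conv block must be c(filters >= 1, kernel >= 1, pool >= 0)")
  structure(list(window_s = window_s, rate_hz = rate_hz,
                 conv_blocks = conv_blocks, dense_units = dense_units,
                 dropout = dropout, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Inverse-frequency class weights
#'
#' `weight_c = N_total / (K_present * N_c)` over the classes present in
#' the training labels, so that `weight_c * N_c` is constant: each
#' present class contributes equally to the weighted loss regardless of
#' its prevalence. Classes absent from training get weight 0 (with a
#' message).
#'
#' @param labels Factor (or character) of training labels.
#' @return Named numeric vector of weights over `levels(labels)` (or the
#'   five activity classes for character input).
#' @export
#' @examples
#' class_weights(factor(rep(c("a", "b"), c(90, 10)), levels = c("a", "b")))
class_weights <- function(labels) {
  if (!is.factor(labels))
    labels <- factor(labels, levels = activity_classes())
  if (length(labels) == 0L) stop("empty label set")
  if (any(is.na(labels))) stop("labels outside the known classes")
  counts <- table(labels)
  present <- counts > 0
  k <- sum(present)
  w <- numeric(length(counts))
  names(w) <- names(counts)
  w[present] <- length(labels) / (k * counts[present])
  if (any(!present))
    message("class(es) absent from training get weight 0: ",
            paste(names(counts)[!present], collapse = ", "))
  w
}

# ---------------------------------------------------------------------------
# architecture planning
# ---------------------------------------------------------------------------

# Resolve the layer dimensions for a given input length. Kernels longer
# than the remaining temporal length are clamped; pooling is skipped when
# fewer than `pool` time steps remain.
plan_architecture <- function(config) {
  L <- round(config$window_s * config$rate_hz)
  input_len <- L
  C <- 3L
  blocks <- list()
  for (bl in config$conv_blocks) {
    filters <- as.integer(bl[1]); kernel <- as.integer(bl[2])
    pool <- as.integer(bl[3])
    k_eff <- min(kernel, L)
    L_out <- L - k_eff + 1L
    do_pool <- pool > 0L && L_out >= pool
    L_pooled <- if (do_pool) L_out %/% pool else L_out
    blocks[[length(blocks) + 1L]] <-
      list(filters = filters, kernel = k_eff, in_channels = C,
           pool = if (do_pool) pool else 0L,
           L_in = L, L_conv = L_out, L_out = L_pooled)
    L <- L_pooled
    C <- filters
  }
  list(input_len = input_len, blocks = blocks, gap_len = L,
       gap_channels = C, dense_units = as.integer(config$dense_units),
       n_classes = length(activity_classes()))
}

#' Build an untrained 1-D CNN activity classifier
#'
#' Initializes a network mapping a `window_len x 3` window to five class
#' probabilities. Initialization is He-normal and deterministic given
#' `config$seed`: two builds with the same seed have identical
#' parameters. At the default 5 s / 50 Hz the input is 250 x 3.
#'
#' @param config A [cnn_config].
#' @return An object of class `cnn_model` (untrained: no normalization
#'   statistics yet).
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  arch <- plan_architecture(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  params <- list()
  for (i in seq_along(arch$blocks)) {
    b <- arch$blocks[[i]]
    fan_in <- b$kernel * b$in_channels
    params[[paste0("Wc", i)]] <-
      matrix(stats::rnorm(fan_in * b$filters, 0, sqrt(2 / fan_in)),
             fan_in, b$filters)
    params[[paste0("bc", i)]] <- numeric(b$filters)
  }
  params$W1 <- matrix(stats::rnorm(arch$gap_channels * arch$dense_units, 0,
                                   sqrt(2 / arch$gap_channels)),
                      arch$gap_channels, arch$dense_units)
  params$b1 <- numeric(arch$dense_units)
  params$W2 <- matrix(stats::rnorm(arch$dense_units * arch$n_classes, 0,
                                   sqrt(2 / arch$dense_units)),
                      arch$dense_units, arch$n_classes)
  params$b2 <- numeric(arch$n_classes)
  structure(list(config = config, arch = arch, params = params,
                 norm = NULL, class_weights = NULL,
                 loss_history = numeric(0), trained = FALSE,
                 classes = activity_classes()),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<cnn_model> input %d x 3 -> %d classes%s\n", a$input_len,
              a$n_classes, if (x$trained) " (trained)" else " (untrained)"))
  for (b in a$blocks)
    cat(sprintf("  conv k=%d filters=%d%s -> length %d\n", b$kernel,
                b$filters,
                if (b$pool > 0) paste0(" pool=", b$pool) else "", b$L_out))
  cat(sprintf("  GAP -> dense %d -> softmax %d; %d parameters\n",
              a$dense_units, a$n_classes,
              sum(vapply(x$params, length, 1L))))
  invisible(x)
}

# gather/scatter index matrices, memoized per (L, k, B) / (Lo, p, B)
.idx_cache <- new.env(parent = emptyenv())

gather_idx <- function(L, k, B) {
  key <- paste("g", L, k, B)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Lo <- L - k + 1L
  base <- rep(seq_len(Lo), times = B) + rep((seq_len(B) - 1L) * L, each = Lo)
  idx <- matrix(0L, Lo * B, k)
  for (j in seq_len(k)) idx[, j] <- base + (j - 1L)
  .idx_cache[[key]] <- idx
  idx
}

pool_idx <- function(Lo, p, B) {
  key <- paste("p", Lo, p, B)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Lp <- Lo %/% p
  base <- rep((seq_len(Lp) - 1L) * p, times = B) +
    rep((seq_len(B) - 1L) * Lo, each = Lp)
  idx <- matrix(0L, Lp * B, p)
  for (q in seq_len(p)) idx[, q] <- base + q
  .idx_cache[[key]] <- idx
  idx
}

add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

# Forward pass over a batch. X is a B x L x 3 array (already
# standardized). Returns softmax probabilities and, if keep_cache, the
# intermediate activations needed for the backward pass.
cnn_forward <- function(arch, params, X, dropout_mask = NULL,
                        keep_cache = FALSE) {
  B <- dim(X)[1L]
  M <- matrix(aperm(X, c(2L, 1L, 3L)), dim(X)[2L] * B, dim(X)[3L])
  cache <- if (keep_cache) list(blocks = vector("list", length(arch$blocks)))
           else NULL
  for (i in seq_along(arch$blocks)) {
    bl <- arch$blocks[[i]]
    idx <- gather_idx(bl$L_in, bl$kernel, B)
    Xcol <- M[as.vector(idx), , drop = FALSE]
    dim(Xcol) <- c(bl$L_conv * B, bl$kernel * bl$in_channels)
    A <- add_bias(Xcol %*% params[[paste0("Wc", i)]],
                  params[[paste0("bc", i)]])
    A[A < 0] <- 0
    if (bl$pool > 0L) {
      pidx <- pool_idx(bl$L_conv, bl$pool, B)
      P <- A[pidx[, 1L], , drop = FALSE]
      takes <- if (keep_cache) vector("list", bl$pool) else NULL
      if (keep_cache) takes[[1L]] <- matrix(TRUE, nrow(P), ncol(P))
      for (q in 2L:bl$pool) {
        Aq <- A[pidx[, q], , drop = FALSE]
        better <- Aq > P
        if (keep_cache) {
          for (r in seq_len(q - 1L)) takes[[r]] <- takes[[r]] & !better
          takes[[q]] <- better
        }
        P[better] <- Aq[better]
      }
      if (keep_cache)
        cache$blocks[[i]] <- list(Xcol = Xcol, act = A, takes = takes)
      M <- P
    } else {
      if (keep_cache) cache$blocks[[i]] <- list(Xcol = Xcol, act = A)
      M <- A
    }
  }
  grp <- rep(seq_len(B), each = arch$gap_len)
  G <- rowsum(M, grp) / arch$gap_len
  H <- add_bias(G %*% params$W1, params$b1)
  H[H < 0] <- 0
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  logits <- add_bias(Hd %*% params$W2, params$b2)
  mx <- apply(logits, 1L, max)
  E <- exp(logits - mx)
  probs <- E / rowSums(E)
  if (keep_cache) {
    cache$G <- G; cache$H <- H; cache$Hd <- Hd
    cache$B <- B
  }
  list(probs = probs, cache = cache)
}

# Backward pass; returns gradients for all parameters.
cnn_backward <- function(arch, params, fw, y_idx, omega, dropout_mask) {
  cache <- fw$cache
  B <- cache$B
  P <- fw$probs
  dlogits <- P
  dlogits[cbind(seq_len(B), y_idx)] <- dlogits[cbind(seq_len(B), y_idx)] - 1
  dlogits <- dlogits * (omega / sum(omega))
  grads <- list()
  grads$W2 <- crossprod(cache$Hd, dlogits)
  grads$b2 <- colSums(dlogits)
  dHd <- dlogits %*% t(params$W2)
  dH <- if (is.null(dropout_mask)) dHd else dHd * dropout_mask
  dH[cache$H <= 0] <- 0
  grads$W1 <- crossprod(cache$G, dH)
  grads$b1 <- colSums(dH)
  dG <- dH %*% t(params$W1)
  dM <- dG[rep(seq_len(B), each = arch$gap_len), , drop = FALSE] /
    arch$gap_len
  for (i in rev(seq_along(arch$blocks))) {
    bl <- arch$blocks[[i]]
    cc <- cache$blocks[[i]]
    if (bl$pool > 0L) {
      pidx <- pool_idx(bl$L_conv, bl$pool, B)
      dA <- matrix(0, bl$L_conv * B, bl$filters)
      for (q in seq_len(bl$pool))
        dA[pidx[, q], ] <- dM * cc$takes[[q]]
    } else {
      dA <- dM
    }
    dA[cc$act <= 0] <- 0
    grads[[paste0("Wc", i)]] <- crossprod(cc$Xcol, dA)
    grads[[paste0("bc", i)]] <- colSums(dA)
    if (i > 1L) {
      dXcol <- dA %*% t(params[[paste0("Wc", i)]])
      idx <- gather_idx(bl$L_in, bl$kernel, B)
      flat <- matrix(dXcol, bl$L_conv * B * bl$kernel, bl$in_channels)
      agg <- rowsum(flat, as.vector(idx))
      dM <- matrix(0, bl$L_in * B, bl$in_channels)
      dM[as.integer(rownames(agg)), ] <- agg
    }
  }
  grads
}

weighted_ce_loss <- function(probs, y_idx, omega) {
  p <- probs[cbind(seq_along(y_idx), y_idx)]
  sum(omega * -log(pmax(p, 1e-12))) / sum(omega)
}

#' Train the CNN on labeled windows
#'
#' Minimizes class-weighted cross-entropy with Adam. Per-channel
#' standardization statistics are computed on the training windows only
#' and stored with the model, so later predictions (including on held-out
#' subjects) reuse the training-fold statistics. Training is
#' deterministic given the data and `config$seed`.
#'
#' @param model An untrained (or previously trained) [build_cnn()] model.
#' @param windows A `window_set`, or an `n x window_len x 3` array.
#' @param labels Factor of window labels over the five activity classes
#'   (taken from the `window_set` if omitted).
#' @param epochs Optional override of `config$epochs`.
#' @param verbose Print per-epoch loss.
#' @return The trained `cnn_model`, with `$loss_history` (mean weighted
#'   cross-entropy per epoch) and `$norm` filled in.
#' @export
train_cnn <- function(model, windows, labels = NULL, epochs = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(windows, "window_set")) {
    labels <- labels %||% windows$label
    windows <- windows$samples
  }
  if (is.null(labels)) stop("labels are required")
  labels <- factor(as.character(labels), levels = model$classes)
  if (any(is.na(labels))) stop("labels outside the five activity classes")
  n <- dim(windows)[1L]
  if (n == 0L) stop("no training windows")
  if (length(labels) != n) stop("labels must match the number of windows")
  if (nlevels(droplevels(labels)) < 2L)
    stop("single-class training data; need at least two classes")
  if (dim(windows)[2L] != model$arch$input_len)
    stop("window length ", dim(windows)[2L], " does not match the model (",
         model$arch$input_len, ")")
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  # per-channel standardization on the training fold only
  mu <- apply(windows, 3L, mean)
  sdev <- pmax(apply(windows, 3L, sd), 1e-8)
  for (c in 1:3) windows[, , c] <- (windows[, , c] - mu[c]) / sdev[c]
  w_class <- class_weights(labels)
  y_idx <- as.integer(labels)
  omega_all <- as.numeric(w_class[y_idx])

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(epochs)
  d_units <- model$arch$dense_units
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_w <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      take <- ord[start:min(start + cfg$batch_size - 1L, n)]
      B <- length(take)
      Xb <- windows[take, , , drop = FALSE]
      yb <- y_idx[take]
      ob <- omega_all[take]
      mask <- if (cfg$dropout > 0)
        matrix((stats::runif(B * d_units) >= cfg$dropout) /
                 (1 - cfg$dropout), B, d_units)
      else NULL
      fw <- cnn_forward(model$arch, params, Xb, dropout_mask = mask,
                        keep_cache = TRUE)
      loss <- weighted_ce_loss(fw$probs, yb, ob)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
      grads <- cnn_backward(model$arch, params, fw, yb, ob, mask)
      step <- step + 1L
      corr1 <- 1 - beta1^step
      corr2 <- 1 - beta2^step
      for (nm in names(params)) {
        g <- grads[[nm]]
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] - cfg$learning_rate *
          (adam_m[[nm]] / corr1) / (sqrt(adam_v[[nm]] / corr2) + eps)
      }
      ep_loss <- ep_loss + loss * sum(ob)
      ep_w <- ep_w + sum(ob)
    }
    loss_hist[ep] <- ep_loss / ep_w
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f", ep, epochs, loss_hist[ep]))
  }
  model$params <- params
  model$norm <- list(mean = mu, sd = sdev)
  model$class_weights <- w_class
  model$loss_history <- loss_hist
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels for windows
#'
#' Standardizes with the statistics stored at training time, runs the
#' forward pass, and takes the argmax with ties broken by the fixed class
#' order (lying < sitting < standing < walking < jogging).
#'
#' @param object A trained `cnn_model`.
#' @param windows A `window_set` or `n x window_len x 3` array matching
#'   the model's input shape.
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return List with `probabilities` (n x 5 matrix, rows summing to 1)
#'   and `labels` (factor).
#' @export
predict.cnn_model <- function(object, windows, batch_size = 256L, ...) {
  if (!object$trained) stop("model has not been trained")
  if (inherits(windows, "window_set")) windows <- windows$samples
  if (length(dim(windows)) != 3L || dim(windows)[2L] != object$arch$input_len ||
      dim(windows)[3L] != 3L)
    stop("windows must be n x ", object$arch$input_len, " x 3")
  n <- dim(windows)[1L]
  for (c in 1:3)
    windows[, , c] <- (windows[, , c] - object$norm$mean[c]) /
      object$norm$sd[c]
  probs <- matrix(NA_real_, n, object$arch$n_classes,
                  dimnames = list(NULL, object$classes))
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    fw <- cnn_forward(object$arch, object$params,
                      windows[take, , , drop = FALSE])
    probs[take, ] <- fw$probs
  }
  labels <- factor(object$classes[max.col(probs, ties.method = "first")],
                   levels = object$classes)
  list(probabilities = probs, labels = labels)
}
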