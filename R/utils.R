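# RNG bookkeeping: functions that seed internally save and restore the
# caller's RNG state so library calls do not perturb user scripts.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# centered moving average with truncated edges (used for HR coupling)
moving_average <- function(x, n_win) {
  n <- length(x)
  left <- (n_win - 1L) %/% 2L
  right <- n_win - 1L - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
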