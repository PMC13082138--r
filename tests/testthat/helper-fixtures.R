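# Shared fixtures; expensive objects are memoized for the whole run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  got <- .fixtures[[key]]
  if (!is.null(got)) return(got)
  val <- force(expr)
  .fixtures[[key]] <- val
  val
}

# short protocol used by cheap tests (one third of the default durations)
short_schedule <- c(lying = 60, sitting = 120, standing = 60,
                    walking = 90, jogging = 45)

small_cohort <- function(n_subjects = 4, seed = 11) {
  memo(paste("cohort", n_subjects, seed),
       generate_cohort(generator_config(n_subjects = n_subjects,
                                        seed = seed,
                                        schedule = short_schedule)))
}

sine_recording <- function(freq_hz, amp = 1, fs = 50, dur_s = 600,
                           subject = "sine") {
  t <- seq(0, dur_s, by = 1 / fs)
  accel_recording(subject, t, amp * sin(2 * pi * freq_hz * t),
                  rep(0, length(t)), rep(0, length(t)),
                  sampling_rate_hz = fs)
}

mag_series <- function(m, fs = 50, subject = "m") {
  structure(list(subject_id = subject, sampling_rate_hz = fs,
                 t = (seq_along(m) - 1) / fs, m = m),
            class = "magnitude_series")
}

# steady-state amplitude of a filtered sinusoid (skips edge transients)
steady_amp <- function(x, skip = 0.25) {
  n <- length(x)
  keep <- seq.int(floor(n * skip), ceiling(n * (1 - skip)))
  max(abs(x[keep]))
}

constant_labels <- function(subject, dur_s, activity = "sitting") {
  label_track(subject, 0, dur_s, activity)
}
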