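#' Synthetic chest-patch cohort configuration
#'
#' The generator emulates the structure of a chest-patch activity
#' protocol: per subject one pass through lying, sitting, standing,
#' walking and jogging blocks with short transition ramps, fidgeting
#' during the seated/standing blocks, one deliberate device-interference
#' burst, and a 1 Hz heart-rate series coupled to movement intensity.
#'
#' Device axes are the generator's own convention: x lateral, y along the
#' torso, z out of the chest. Gravity lies along -y when upright and -z
#' when lying. Signals that survive the 0.05-2 Hz analysis band are
#' posture-specific on purpose: respiration-driven chest motion
#' (~0.25 Hz) acts along the anterior-posterior z axis in every posture
#' but with larger excursion when supine, postural sway (0.1-1 Hz) is
#' present only while standing, and gait carries a stride-frequency
#' (half the step frequency) lateral component alongside the step
#' fundamental and its second harmonic. Distinguishing the static
#' postures therefore requires resolving the amplitude of a slow
#' oscillation (at least one respiratory cycle of context), not just an
#' instantaneous offset. Broadband noise above 2 Hz is injected on all
#' axes so that widening the filter's high cutoff admits noise without
#' adding information.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param seed Integer master seed; each subject derives its own stream.
#' @param rate_hz Accelerometer sampling rate (default 50).
#' @param schedule Named numeric vector of block durations in seconds, in
#'   protocol order.
#' @param duration_jitter Relative jitter applied per subject and block
#'   (default 0.3, i.e. durations vary by +/-30%).
#' @param transition_range_s Range of transition-ramp durations.
#' @param walking_freq_hz,jogging_freq_hz Step-frequency ranges (uniform
#'   draws per subject).
#' @param walking_amp_g,jogging_amp_g Step-acceleration amplitude ranges.
#' @param gait_harmonic,gait_crosstalk Relative amplitudes of the
#'   vertical second harmonic and the anterior-posterior crosstalk at
#'   the step frequency.
#' @param gait_stride Named vector of relative amplitudes of the lateral
#'   stride-frequency (half the step frequency) component for walking
#'   and jogging. Running involves markedly stronger stride-frequency
#'   trunk oscillation than walking, which also keeps measured in-band
#'   intensity ordered with effort once the 2 Hz analysis low-pass has
#'   attenuated the jogging step fundamental.
#' @param static_noise_sd_g White sensor noise during static blocks.
#' @param resp_freq_hz,resp_amp_g Respiration frequency and amplitude
#'   ranges (amplitude drawn for the upright postures).
#' @param resp_lying_factor Multiplier on the respiration amplitude when
#'   lying (supine breathing moves the chest wall further along the
#'   anterior-posterior axis).
#' @param sway_sd_g RMS of the 0.1-1 Hz postural-sway noise (standing).
#' @param fidget_rate_per_min,fidget_dur_s,fidget_amp_g Fidget burst
#'   rate, duration range, amplitude range (sitting and standing).
#' @param hf_noise_sd_g SD of the broadband noise high-passed at 2 Hz.
#' @param interference_dur_s Duration range of the interference burst.
#' @param hr_baseline_mean_bpm,hr_baseline_sd_bpm Resting heart-rate
#'   distribution across subjects.
#' @param hr_gain_bpm_per_g Heart-rate response per g of smoothed
#'   movement magnitude.
#' @param hr_noise_sd_bpm,hr_noise_ar Marginal SD and lag-1 coefficient
#'   of the AR(1) heart-rate noise.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 10, seed = 1L, rate_hz = 50,
                             schedule = c(lying = 180, sitting = 360,
                                          standing = 180, walking = 300,
                                          jogging = 120),
                             duration_jitter = 0.3,
                             transition_range_s = c(3, 8),
                             walking_freq_hz = c(1.4, 2.2),
                             jogging_freq_hz = c(2.4, 3.2),
                             walking_amp_g = c(0.25, 0.45),
                             jogging_amp_g = c(0.6, 1.0),
                             gait_harmonic = 0.5, gait_crosstalk = 0.3,
                             gait_stride = c(walking = 0.25,
                                             jogging = 0.5),
                             static_noise_sd_g = 0.01,
                             resp_freq_hz = c(0.2, 0.3),
                             resp_amp_g = c(0.008, 0.015),
                             resp_lying_factor = 2.5,
                             sway_sd_g = 0.015,
                             fidget_rate_per_min = 2,
                             fidget_dur_s = c(1, 3),
                             fidget_amp_g = c(0.05, 0.15),
                             hf_noise_sd_g = 0.02,
                             interference_dur_s = c(3, 6),
                             hr_baseline_mean_bpm = 65,
                             hr_baseline_sd_bpm = 5,
                             hr_gain_bpm_per_g = 60,
                             hr_noise_sd_bpm = 2, hr_noise_ar = 0.9) {
  stopifnot(n_subjects >= 1, rate_hz > 0, all(schedule > 0),
            duration_jitter >= 0, duration_jitter < 1)
  if (sum(schedule) > 24 * 3600) stop("schedule exceeds 24 h")
  if (max(jogging_freq_hz) * 2 >= rate_hz / 2)
    stop("jogging harmonic would exceed the Nyquist frequency")
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

# fixed component phase offsets (radians); deterministic so that the
# coupling analysis in expected_coupling_rho() sees the same waveform
gait_phases <- c(step = 0, harmonic = 0.7, crosstalk = 1.3, stride = 2.1)

subject_seed <- function(config, subject_index) {
  as.integer((as.numeric(config$seed) * 7919 + subject_index) %% 2147483629)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# band-limited Gaussian noise with a target marginal SD
band_noise <- function(n, fs, band, sd_target) {
  raw <- stats::rnorm(n + 200L)
  filt <- signal::butter(2, pmin(band, fs / 2 * 0.99) / (fs / 2),
                         type = "pass")
  out <- as.numeric(signal::filtfilt(filt, raw))[101:(n + 100L)]
  s <- stats::sd(out)
  if (s < 1e-12) return(numeric(n))
  out * (sd_target / s)
}

# white noise high-passed above `cut` Hz
hf_noise <- function(n, fs, cut, sd_target) {
  raw <- stats::rnorm(n + 200L, 0, sd_target)
  filt <- signal::butter(4, cut / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(filt, raw))[101:(n + 100L)]
}

# gravity unit vector by posture
posture_gravity <- function(activity) {
  if (activity == "lying") c(0, 0, -1) else c(0, -1, 0)
}

# gait waveform on the three axes for elapsed block time tt (seconds)
gait_signal <- function(tt, amp, freq, activity, config) {
  ph <- gait_phases
  stride <- config$gait_stride[[activity]]
  y <- amp * sin(2 * pi * freq * tt + ph[["step"]]) +
    config$gait_harmonic * amp * sin(4 * pi * freq * tt + ph[["harmonic"]])
  z <- config$gait_crosstalk * amp * sin(2 * pi * freq * tt +
                                           ph[["crosstalk"]])
  x <- stride * amp * sin(pi * freq * tt + ph[["stride"]])
  list(x = x, y = y, z = z)
}

# 1-s cosine taper at both block edges, so activity fades in and out
edge_taper <- function(n, fs) {
  k <- min(n %/% 2, round(fs))
  env <- rep(1, n)
  if (k > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(k) / k))
    env[seq_len(k)] <- ramp
    env[n + 1L - seq_len(k)] <- rev(ramp)
  }
  env
}

#' Generate one synthetic subject
#'
#' Deterministic given `(config$seed, subject_index)`. Returns the
#' accelerometry recording, the interval label track (activity blocks,
#' transition ramps and one interference burst), the coupled 1 Hz
#' heart-rate series, and the drawn ground-truth parameters.
#'
#' @param config A [generator_config].
#' @param subject_index Subject number (1-based).
#' @return List with elements `accel`, `labels`, `hr`, `params`.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "generator_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(subject_seed(config, subject_index))
  fs <- config$rate_hz
  id <- sprintf("subj%02d", subject_index)

  params <- list(
    subject_id = id,
    walking_freq_hz = runif1(config$walking_freq_hz),
    jogging_freq_hz = runif1(config$jogging_freq_hz),
    walking_amp_g = runif1(config$walking_amp_g),
    jogging_amp_g = runif1(config$jogging_amp_g),
    resp_freq_hz = runif1(config$resp_freq_hz),
    resp_amp_g = runif1(config$resp_amp_g),
    hr_baseline_bpm = stats::rnorm(1, config$hr_baseline_mean_bpm,
                                   config$hr_baseline_sd_bpm))

  acts <- names(config$schedule)
  durs <- config$schedule *
    stats::runif(length(config$schedule), 1 - config$duration_jitter,
                 1 + config$duration_jitter)
  ramps <- stats::runif(length(acts) - 1L, config$transition_range_s[1],
                        config$transition_range_s[2])
  params$block_durations_s <- as.list(stats::setNames(durs, acts))

  # interval schedule: block, ramp, block, ...
  starts <- ends <- numeric(0); labels <- character(0)
  t_at <- 0
  for (i in seq_along(acts)) {
    starts <- c(starts, t_at); ends <- c(ends, t_at + durs[i])
    labels <- c(labels, acts[i])
    t_at <- t_at + durs[i]
    if (i < length(acts)) {
      starts <- c(starts, t_at); ends <- c(ends, t_at + ramps[i])
      labels <- c(labels, "transition")
      t_at <- t_at + ramps[i]
    }
  }
  total_s <- t_at
  n <- floor(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n); y <- numeric(n); z <- numeric(n)

  # gravity orientation with cosine interpolation across ramps
  gvec <- matrix(0, n, 3L)
  for (i in seq_along(labels)) {
    idx <- which(t >= starts[i] & t < ends[i])
    if (!length(idx)) next
    if (labels[i] != "transition") {
      g <- posture_gravity(labels[i])
      gvec[idx, ] <- matrix(g, length(idx), 3L, byrow = TRUE)
    } else {
      g0 <- posture_gravity(labels[i - 1L])
      g1 <- posture_gravity(labels[i + 1L])
      w <- 0.5 * (1 - cos(pi * (t[idx] - starts[i]) / (ends[i] - starts[i])))
      gvec[idx, ] <- outer(1 - w, g0) + outer(w, g1)
    }
  }

  fidget_log <- list()
  for (i in seq_along(labels)) {
    act <- labels[i]
    idx <- which(t >= starts[i] & t < ends[i])
    if (!length(idx)) next
    tt <- t[idx] - starts[i]
    nb <- length(idx)
    if (act %in% c("walking", "jogging")) {
      amp <- if (act == "walking") params$walking_amp_g else
        params$jogging_amp_g
      freq <- if (act == "walking") params$walking_freq_hz else
        params$jogging_freq_hz
      g <- gait_signal(tt, amp, freq, act, config)
      env <- edge_taper(nb, fs)
      x[idx] <- x[idx] + env * g$x
      y[idx] <- y[idx] + env * g$y
      z[idx] <- z[idx] + env * g$z
    } else if (act %in% c("lying", "sitting", "standing")) {
      # respiration along the anterior-posterior axis; deeper when supine
      resp_amp <- params$resp_amp_g *
        if (act == "lying") config$resp_lying_factor else 1
      z[idx] <- z[idx] + resp_amp *
        sin(2 * pi * params$resp_freq_hz * (t[idx]))
      # sensor noise during static blocks
      x[idx] <- x[idx] + stats::rnorm(nb, 0, config$static_noise_sd_g)
      y[idx] <- y[idx] + stats::rnorm(nb, 0, config$static_noise_sd_g)
      z[idx] <- z[idx] + stats::rnorm(nb, 0, config$static_noise_sd_g)
      if (act == "standing") {
        x[idx] <- x[idx] + band_noise(nb, fs, c(0.1, 1), config$sway_sd_g)
        z[idx] <- z[idx] + band_noise(nb, fs, c(0.1, 1), config$sway_sd_g)
      }
      if (act %in% c("sitting", "standing")) {
        n_fid <- stats::rpois(1, config$fidget_rate_per_min *
                                (ends[i] - starts[i]) / 60)
        for (k in seq_len(n_fid)) {
          dur <- runif1(config$fidget_dur_s)
          amp <- runif1(config$fidget_amp_g)
          at <- stats::runif(1, starts[i], max(starts[i],
                                               ends[i] - dur))
          fi <- which(t >= at & t < at + dur)
          if (!length(fi)) next
          env <- edge_taper(length(fi), fs / 2)
          x[fi] <- x[fi] + env * band_noise(length(fi), fs, c(0.3, 3),
                                            amp * 0.6)
          y[fi] <- y[fi] + env * band_noise(length(fi), fs, c(0.3, 3), amp)
          z[fi] <- z[fi] + env * band_noise(length(fi), fs, c(0.3, 3),
                                            amp * 0.6)
          fidget_log[[length(fidget_log) + 1L]] <-
            c(start_s = at, dur_s = dur, amp_g = amp)
        }
      }
    } else {
      # transition ramp: repositioning movement
      mv <- edge_taper(nb, fs)
      x[idx] <- x[idx] + mv * band_noise(nb, fs, c(0.5, 3), 0.05)
      y[idx] <- y[idx] + mv * band_noise(nb, fs, c(0.5, 3), 0.08)
      z[idx] <- z[idx] + mv * band_noise(nb, fs, c(0.5, 3), 0.05)
    }
  }

  # one deliberate interference burst inside the sitting block
  sit <- which(labels == "sitting")[1L]
  int_dur <- runif1(config$interference_dur_s)
  int_at <- stats::runif(1, starts[sit] + 10,
                         max(starts[sit] + 10, ends[sit] - int_dur - 10))
  ii <- which(t >= int_at & t < int_at + int_dur)
  if (length(ii)) {
    spikes <- stats::rbinom(length(ii), 1, 5 / fs) *
      stats::runif(length(ii), 0.3, 1) *
      sign(stats::runif(length(ii)) - 0.5)
    x[ii] <- x[ii] + spikes * 0.5
    y[ii] <- y[ii] + spikes
    z[ii] <- z[ii] + spikes * 0.7
    # split the sitting interval around the burst
    starts <- c(starts, int_at, int_at + int_dur)
    ends <- c(ends, int_at + int_dur, ends[sit])
    labels <- c(labels, "interference", "sitting")
    ends[sit] <- int_at
    params$interference <- c(start_s = int_at, dur_s = int_dur)
  }
  params$fidgets <- fidget_log

  # broadband noise above the 2 Hz analysis band, all axes
  x <- x + hf_noise(n, fs, 2, config$hf_noise_sd_g)
  y <- y + hf_noise(n, fs, 2, config$hf_noise_sd_g)
  z <- z + hf_noise(n, fs, 2, config$hf_noise_sd_g)

  # movement magnitude (gravity excluded) drives the heart rate
  mv_mag <- sqrt((x)^2 + (y)^2 + (z)^2)
  x <- x + gvec[, 1L]; y <- y + gvec[, 2L]; z <- z + gvec[, 3L]

  driver <- moving_average(mv_mag, max(3L, round(2 * fs)))
  hr_t <- seq(0, floor(total_s) - 1L)
  hr_idx <- pmin(n, round(hr_t * fs) + 1L)
  phi <- config$hr_noise_ar
  innov_sd <- config$hr_noise_sd_bpm * sqrt(1 - phi^2)
  ar <- as.numeric(stats::filter(stats::rnorm(length(hr_t), 0, innov_sd),
                                 phi, method = "recursive"))
  hr_vals <- pmax(30, params$hr_baseline_bpm +
                    config$hr_gain_bpm_per_g * driver[hr_idx] + ar)

  list(accel = accel_recording(id, t, x, y, z, sampling_rate_hz = fs),
       labels = label_track(id, starts, ends, labels),
       hr = hr_series(id, hr_t, hr_vals),
       params = params)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n_subjects` subjects (deterministically given the seed)
#' and optionally writes them as CSV triples in the package's on-disk
#' dialects plus a `manifest.json` recording all drawn ground-truth
#' parameters.
#'
#' @param config A [generator_config].
#' @param dir Output directory; created if needed. `NULL` (default)
#'   keeps the cohort in memory only.
#' @return List of subjects (each with `accel`, `labels`, `hr`,
#'   `params`), invisibly when writing to disk; the manifest is attached
#'   as attribute `"manifest"`.
#' @export
generate_cohort <- function(config = generator_config(), dir = NULL) {
  cohort <- lapply(seq_len(config$n_subjects),
                   function(i) generate_subject(config, i))
  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    rate_hz = config$rate_hz,
    subjects = lapply(cohort, `[[`, "params"))
  attr(cohort, "manifest") <- manifest
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in cohort) {
      id <- s$accel$subject_id
      write_accel(s$accel, file.path(dir, paste0(id, "_accel.csv")))
      write_labels(s$labels, file.path(dir, paste0(id, "_labels.csv")))
      write_hr(s$hr, file.path(dir, paste0(id, "_hr.csv")))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(cohort))
  }
  cohort
}

#' Read a cohort directory written by [generate_cohort()]
#'
#' @param dir Directory containing `<id>_accel.csv`, `<id>_labels.csv`,
#'   `<id>_hr.csv` triples.
#' @return List of subjects with elements `accel`, `labels`, `hr`.
#' @export
read_cohort <- function(dir) {
  accel_files <- sort(list.files(dir, "_accel\\.csv$", full.names = TRUE))
  if (!length(accel_files)) stop("no *_accel.csv files in ", dir)
  lapply(accel_files, function(f) {
    stem <- sub("_accel\\.csv$", "", f)
    list(accel = read_accel(f),
         labels = read_labels(paste0(stem, "_labels.csv")),
         hr = read_hr(paste0(stem, "_hr.csv")))
  })
}

#' Ground-truth active/inactive separation point of a cohort
#'
#' The midpoint between the bulk upper edge of the inactive window-value
#' distribution (99.5% quantile over lying/sitting/standing windows) and
#' the bulk lower edge of the active distribution (0.5% quantile over
#' walking/jogging windows), computed from true labels. Quantile edges
#' rather than the extremes keep the boundary robust to the rare extreme
#' fidget burst or soft locomotion window the generator legitimately
#' produces. An overlap-minimizing calibration should land inside this
#' gap, i.e. close to the midpoint.
#'
#' @param cohort List of subjects with `accel` and `labels`.
#' @param config A [cutpoint_config] (window duration, metric).
#' @param spec A [filter_spec].
#' @param minutes Truncation budget in minutes.
#' @return List with `separation_g` (gap midpoint), `inactive_edge_g`,
#'   `active_edge_g`, and the pooled per-window table.
#' @export
cohort_separation_point <- function(cohort, config = cutpoint_config(),
                                    spec = filter_spec(), minutes = 20) {
  tabs <- lapply(cohort, function(s)
    cutpoint_windows(s$accel, s$labels, config, spec, minutes))
  tab <- do.call(rbind, tabs)
  lo <- stats::quantile(tab$value[tab$truth == "inactive"], 0.995,
                        names = FALSE)
  hi <- stats::quantile(tab$value[tab$truth == "active"], 0.005,
                        names = FALSE)
  list(separation_g = (lo + hi) / 2, inactive_edge_g = lo,
       active_edge_g = hi, windows = tab)
}

#' Design value of the movement/heart-rate coupling correlation
#'
#' Computes the Pearson correlation implied by the generator's own
#' construction between the per-window rolling-median band-passed
#' magnitude and the heart-rate deviation over active windows, by
#' deterministic quadrature over the configured gait parameter ranges.
#' For each (activity, amplitude, step frequency) node the gait waveform
#' is evaluated over one stride cycle; the heart-rate driver is the mean
#' raw movement magnitude and the measured intensity is the median
#' band-filtered magnitude (zero-phase Butterworth gains applied per
#' spectral component). Mixture moments over the uniform parameter
#' ranges (weighted by scheduled block durations) then give
#' `rho = g cov(d, m) / sqrt((g^2 var(d) + sigma^2) var(m))`
#' with `g` the heart-rate gain and `sigma` the marginal AR(1) noise SD.
#' Within-block waveform fluctuations are neglected, so the value is the
#' design correlation of the block-level mixture, not of any finite
#' sample.
#'
#' @param config A [generator_config].
#' @param spec The [filter_spec] assumed for the measured magnitude.
#' @param n_quad Quadrature nodes per parameter dimension.
#' @return The design correlation (numeric scalar in \\[-1, 1\\]).
#' @export
expected_coupling_rho <- function(config = generator_config(),
                                  spec = filter_spec(), n_quad = 9) {
  # band-pass amplitude gain at frequency f: |H| for a single causal
  # pass, |H|^2 for the forward-backward zero-phase pass
  amp_gain <- function(f) {
    lp <- 1 / (1 + (f / spec$high_hz)^(2 * spec$order))
    hp <- if (spec$low_hz > 0) (f / spec$low_hz)^(2 * spec$order) /
      (1 + (f / spec$low_hz)^(2 * spec$order)) else 1
    if (spec$mode == "zero_phase") lp * hp else sqrt(lp * hp)
  }
  node_vals <- function(amp, freq, activity) {
    tt <- seq(0, 2 / freq, length.out = 400L)
    g <- gait_signal(tt, amp, freq, activity, config)
    d <- mean(sqrt(g$x^2 + g$y^2 + g$z^2 + 3 * config$hf_noise_sd_g^2))
    ph <- gait_phases
    yf <- amp * amp_gain(freq) * sin(2 * pi * freq * tt + ph[["step"]]) +
      config$gait_harmonic * amp * amp_gain(2 * freq) *
        sin(4 * pi * freq * tt + ph[["harmonic"]])
    zf <- config$gait_crosstalk * amp * amp_gain(freq) *
      sin(2 * pi * freq * tt + ph[["crosstalk"]])
    xf <- config$gait_stride[[activity]] * amp * amp_gain(freq / 2) *
      sin(pi * freq * tt + ph[["stride"]])
    m <- stats::median(sqrt(xf^2 + yf^2 + zf^2))
    c(d = d, m = m)
  }
  share <- config$schedule[c("walking", "jogging")]
  share <- share / sum(share)
  qa <- function(range) seq(range[1], range[2], length.out = n_quad)
  moments <- c(w = 0, d = 0, m = 0, dd = 0, mm = 0, dm = 0)
  for (act in c("walking", "jogging")) {
    a_range <- if (act == "walking") config$walking_amp_g else
      config$jogging_amp_g
    f_range <- if (act == "walking") config$walking_freq_hz else
      config$jogging_freq_hz
    wt <- share[[act]] / n_quad^2
    for (a in qa(a_range)) for (f in qa(f_range)) {
      v <- node_vals(a, f, act)
      moments <- moments + wt * c(1, v[["d"]], v[["m"]], v[["d"]]^2,
                                  v[["m"]]^2, v[["d"]] * v[["m"]])
    }
  }
  var_d <- moments[["dd"]] - moments[["d"]]^2
  var_m <- moments[["mm"]] - moments[["m"]]^2
  cov_dm <- moments[["dm"]] - moments[["d"]] * moments[["m"]]
  g <- config$hr_gain_bpm_per_g
  sigma2 <- config$hr_noise_sd_bpm^2
  (g * cov_dm) / sqrt((g^2 * var_d + sigma2) * var_m)
}
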