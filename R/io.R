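#' Construct and validate a triaxial accelerometry recording
#'
#' An `accel_recording` holds one subject's triaxial acceleration series in
#' units of g on a time axis in seconds from recording start. Validation
#' enforces strictly increasing time, finite accelerations, and agreement
#' between the declared sampling rate and the median inter-sample gap
#' (within 10%).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param x,y,z Numeric vectors of per-axis acceleration in g, same length
#'   as `t`.
#' @param sampling_rate_hz Sampling rate in Hz. If `NULL`, estimated as
#'   `1/median(diff(t))` and snapped to the nearest common device rate
#'   (5, 10, 25, 50, 100, 128 Hz) when within 2%.
#' @return An object of class `accel_recording`.
#' @export
#' @examples
#' rec <- accel_recording("s1", t = seq(0, 1, by = 0.02),
#'                        x = rnorm(51, 0, 0.01), y = rnorm(51, -1, 0.01),
#'                        z = rnorm(51, 0, 0.01))
#' rec$sampling_rate_hz
accel_recording <- function(subject_id, t, x, y, z, sampling_rate_hz = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(t)
  if (n < 2L) stop("accel recording needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("t, x, y, z must all have the same length")
  bad_t <- which(!is.finite(t))
  if (length(bad_t)) stop("non-finite time at row ", bad_t[1L])
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) stop("non-monotone time at row ", nonmono[1L] + 1L)
  for (ax in list(x = x, y = y, z = z)) {
    bad <- which(!is.finite(ax))
    if (length(bad)) stop("non-finite acceleration at row ", bad[1L])
  }
  gap <- stats::median(diff(t))
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- snap_rate(1 / gap)
  } else {
    if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
      stop("sampling_rate_hz must be a positive number")
    if (abs(gap - 1 / sampling_rate_hz) > 0.1 / sampling_rate_hz)
      stop("median inter-sample gap (", signif(gap, 6),
           " s) inconsistent with sampling rate ", sampling_rate_hz, " Hz")
  }
  structure(
    list(subject_id = subject_id, sampling_rate_hz = sampling_rate_hz,
         t = t, x = x, y = y, z = z),
    class = "accel_recording")
}

# snap an estimated rate to the nearest common device rate when within 2%
snap_rate <- function(rate_est) {
  common <- c(5, 10, 25, 50, 100, 128)
  rel <- abs(common - rate_est) / common
  i <- which.min(rel)
  if (rel[i] <= 0.02) common[i] else rate_est
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s: %d samples @ %g Hz, %.1f s\n",
              x$subject_id, length(x$t), x$sampling_rate_hz,
              x$t[length(x$t)] - x$t[1L]))
  invisible(x)
}

#' Construct and validate an interval label track
#'
#' A `label_track` is an ordered set of non-overlapping timed intervals,
#' each carrying one of the five activity classes or one of the markers
#' `transition` / `interference`. Activity words are matched
#' case-insensitively and normalized to lowercase; anything outside the
#' closed vocabulary is an error.
#'
#' @param subject_id Character scalar.
#' @param start_s,end_s Numeric vectors of interval bounds in seconds,
#'   with `start_s < end_s` elementwise.
#' @param activity Character vector of interval labels.
#' @return An object of class `label_track` with a data frame `$intervals`
#'   sorted by start time.
#' @export
#' @examples
#' label_track("s1", c(0, 60, 65), c(60, 65, 120),
#'             c("sitting", "transition", "walking"))
label_track <- function(subject_id, start_s, end_s, activity) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  activity <- tolower(trimws(as.character(activity)))
  n <- length(start_s)
  if (length(end_s) != n || length(activity) != n)
    stop("start_s, end_s, activity must have the same length")
  if (n == 0L) stop("label track has no intervals")
  unknown <- setdiff(unique(activity), label_vocabulary())
  if (length(unknown))
    stop("unknown activity word(s): ", paste(unknown, collapse = ", "))
  bad <- which(!(start_s < end_s))
  if (length(bad)) stop("interval ", bad[1L], " has start_s >= end_s")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]; activity <- activity[o]
  if (n > 1L) {
    ov <- which(start_s[-1L] < end_s[-n])
    if (length(ov))
      stop(sprintf("overlapping intervals: [%g, %g] %s and [%g, %g] %s",
                   start_s[ov[1L]], end_s[ov[1L]], activity[ov[1L]],
                   start_s[ov[1L] + 1L], end_s[ov[1L] + 1L],
                   activity[ov[1L] + 1L]))
  }
  structure(
    list(subject_id = subject_id,
         intervals = data.frame(start_s = start_s, end_s = end_s,
                                activity = activity,
                                stringsAsFactors = FALSE)),
    class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> subject %s: %d intervals over [%g, %g] s\n",
              x$subject_id, nrow(x$intervals), min(x$intervals$start_s),
              max(x$intervals$end_s)))
  invisible(x)
}

#' Construct and validate a heart-rate series
#'
#' A 1 Hz (nominal) heart-rate series in beats per minute. Time must be
#' increasing and all values finite and positive.
#'
#' @param subject_id Character scalar.
#' @param t Numeric vector of sample times in seconds.
#' @param hr_bpm Numeric vector of heart rates in bpm, same length as `t`.
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(subject_id, t, hr_bpm) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  t <- as.numeric(t); hr_bpm <- as.numeric(hr_bpm)
  if (length(t) == 0L) stop("no samples")
  if (length(hr_bpm) != length(t)) stop("t and hr_bpm must have the same length")
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) stop("non-monotone time at row ", nonmono[1L] + 1L)
  bad <- which(!is.finite(hr_bpm) | hr_bpm <= 0)
  if (length(bad))
    stop("non-positive or non-finite hr_bpm at row ", bad[1L])
  structure(list(subject_id = subject_id, t = t, hr_bpm = hr_bpm),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> subject %s: %d samples, median %.0f bpm\n",
              x$subject_id, length(x$t), stats::median(x$hr_bpm)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV readers / writers
#
# Dialects:
#   accel:  time_s,x_g,y_g,z_g   (optional leading "# subject_id=<id>" line)
#   labels: start_s,end_s,activity
#   hr:     time_s,hr_bpm
# ---------------------------------------------------------------------------

read_csv_with_subject <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  subject <- NULL
  skip <- 0L
  if (length(first) && grepl("^#\\s*subject_id\\s*=", first)) {
    subject <- trimws(sub("^#\\s*subject_id\\s*=", "", first))
    skip <- 1L
  }
  df <- tryCatch(
    utils::read.csv(path, skip = skip, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (is.null(subject))
    subject <- sub("\\.[^.]*$", "", basename(path))
  list(df = df, subject = subject)
}

#' Read a triaxial accelerometry CSV
#'
#' Expects columns `time_s,x_g,y_g,z_g`; an optional first line
#' `# subject_id=<id>` sets the subject, otherwise the filename stem is
#' used. The sampling rate is estimated from the median inter-sample gap
#' and snapped to the nearest common device rate when within 2%.
#'
#' @param path Path to the CSV file.
#' @param units Units of the stored axes: `"g"` (default, no conversion)
#'   or `"m/s2"` (divided by 9.80665 on ingest).
#' @return An [accel_recording].
#' @export
read_accel <- function(path, units = c("g", "m/s2")) {
  units <- match.arg(units)
  got <- read_csv_with_subject(path, c("time_s", "x_g", "y_g", "z_g"))
  df <- got$df
  if (nrow(df) == 0L) stop("no samples in ", path)
  scale <- if (units == "m/s2") 1 / 9.80665 else 1
  accel_recording(got$subject, df$time_s,
                  df$x_g * scale, df$y_g * scale, df$z_g * scale)
}

#' Write a triaxial accelerometry CSV
#'
#' Inverse of [read_accel()]; writes full precision so a read/write round
#' trip reproduces all fields to at least 9 decimal digits.
#'
#' @param recording An [accel_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel <- function(recording, path) {
  stopifnot(inherits(recording, "accel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# subject_id=", recording$subject_id), con)
  df <- data.frame(time_s = recording$t, x_g = recording$x,
                   y_g = recording$y, z_g = recording$z)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an interval label CSV
#'
#' Expects columns `start_s,end_s,activity`. Activity words are matched
#' case-insensitively; unknown words and overlapping intervals are errors.
#'
#' @inheritParams read_accel
#' @return A [label_track], sorted by start time.
#' @export
read_labels <- function(path) {
  got <- read_csv_with_subject(path, c("start_s", "end_s", "activity"))
  if (nrow(got$df) == 0L) stop("no intervals in ", path)
  label_track(got$subject, got$df$start_s, got$df$end_s, got$df$activity)
}

#' Write an interval label CSV
#'
#' @param labels A [label_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# subject_id=", labels$subject_id), con)
  utils::write.csv(format(labels$intervals, digits = 15,
                          scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heart-rate CSV
#'
#' Expects columns `time_s,hr_bpm`; values must be finite and positive.
#'
#' @inheritParams read_accel
#' @return An [hr_series].
#' @export
read_hr <- function(path) {
  got <- read_csv_with_subject(path, c("time_s", "hr_bpm"))
  if (nrow(got$df) == 0L) stop("no samples in ", path)
  hr_series(got$subject, got$df$time_s, got$df$hr_bpm)
}

#' Write a heart-rate CSV
#'
#' @param hr An [hr_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hr <- function(hr, path) {
  stopifnot(inherits(hr, "hr_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# subject_id=", hr$subject_id), con)
  utils::write.csv(format(data.frame(time_s = hr$t, hr_bpm = hr$hr_bpm),
                          digits = 15, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
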