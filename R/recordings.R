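#' Sensor-stream containers
#'
#' A `cane_recording` holds the time-stamped channels logged by the
#' instrumented cane: strain-gauge output in ADC counts, a 3-axis gyroscope
#' in degrees per second, and a 3-axis accelerometer in g.  The gyroscope
#' x axis is the mediolateral axis, so `gyro_x` is the cane anteroposterior
#' (AP) angular velocity used throughout segmentation.  A `shank_recording`
#' holds the single AP angular-velocity channel of a shank-mounted IMU.
#'
#' @param time numeric vector of sample times in seconds, uniformly spaced.
#' @param strain strain-gauge signal, ADC counts (signed once
#'   baseline-corrected).
#' @param gyro_x,gyro_y,gyro_z gyroscope channels, degrees/s.  `gyro_x` is the
#'   cane AP velocity.  Missing channels are filled with zeros and flagged in
#'   `meta$missing_channels`.
#' @param accel_x,accel_y,accel_z accelerometer channels, g.
#' @param sample_rate sampling frequency in Hz; inferred from `time` when
#'   `NULL`.
#' @param gyro_range gyroscope full-scale range, degrees/s.
#' @param accel_range accelerometer full-scale range, g.
#' @param meta named list of free-form labels (participant, condition,
#'   cane_length_m, applied filter specs, ...).
#' @return An object of class `cane_recording` (resp. `shank_recording`).
#' @export
cane_recording <- function(time, strain, gyro_x = NULL, gyro_y = NULL,
                           gyro_z = NULL, accel_x = NULL, accel_y = NULL,
                           accel_z = NULL, sample_rate = NULL,
                           gyro_range = 500, accel_range = 16,
                           meta = list()) {
  n <- length(time)
  missing <- character(0)
  fill <- function(x, name) {
    if (is.null(x)) {
      missing <<- c(missing, name)
      return(numeric(n))
    }
    as.numeric(x)
  }
  rec <- structure(list(
    time = as.numeric(time),
    strain = as.numeric(strain),
    gyro_x = fill(gyro_x, "gyro_x"),
    gyro_y = fill(gyro_y, "gyro_y"),
    gyro_z = fill(gyro_z, "gyro_z"),
    accel_x = fill(accel_x, "accel_x"),
    accel_y = fill(accel_y, "accel_y"),
    accel_z = fill(accel_z, "accel_z"),
    sample_rate = if (is.null(sample_rate)) infer_rate(time) else sample_rate,
    gyro_range = gyro_range,
    accel_range = accel_range,
    meta = meta
  ), class = "cane_recording")
  if (length(missing)) rec$meta$missing_channels <- missing
  validate_recording(rec)
  rec
}

#' @rdname cane_recording
#' @param gyro_ap shank AP (mediolateral-axis) angular velocity, degrees/s.
#' @export
shank_recording <- function(time, gyro_ap, sample_rate = NULL, meta = list()) {
  rec <- structure(list(
    time = as.numeric(time),
    gyro_ap = as.numeric(gyro_ap),
    sample_rate = if (is.null(sample_rate)) infer_rate(time) else sample_rate,
    meta = meta
  ), class = "shank_recording")
  validate_recording(rec)
  rec
}

infer_rate <- function(time) {
  if (length(time) < 2L) stop("cannot infer sample rate from < 2 samples", call. = FALSE)
  1 / stats::median(diff(time))
}

channel_names <- function(rec) {
  setdiff(names(rec), c("time", "sample_rate", "gyro_range", "accel_range", "meta"))
}

validate_recording <- function(rec) {
  n <- length(rec$time)
  if (n < 1L) stop("recording is empty", call. = FALSE)
  for (ch in channel_names(rec)) {
    if (length(rec[[ch]]) != n)
      stop(sprintf("channel '%s' length %d != time length %d", ch, length(rec[[ch]]), n),
           call. = FALSE)
  }
  if (n >= 2L) {
    dt <- diff(rec$time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("time must be uniform within 1% jitter", call. = FALSE)
  }
  if (!is.numeric(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  invisible(rec)
}

#' @export
print.cane_recording <- function(x, ...) {
  cat(sprintf("<cane_recording> %d samples @ %.1f Hz (%.1f s)\n",
              length(x$time), x$sample_rate, diff(range(x$time))))
  cat(sprintf("  strain [%0.1f, %0.1f] counts; gyro_x [%0.1f, %0.1f] deg/s\n",
              min(x$strain), max(x$strain), min(x$gyro_x), max(x$gyro_x)))
  if (length(x$meta)) {
    lab <- x$meta[vapply(x$meta, function(v) is.character(v) || is.numeric(v), TRUE)]
    lab <- lab[vapply(lab, length, 0L) == 1L]
    if (length(lab))
      cat("  meta:", paste(names(lab), unlist(lab), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.shank_recording <- function(x, ...) {
  cat(sprintf("<shank_recording> %d samples @ %.1f Hz (%.1f s)\n",
              length(x$time), x$sample_rate, diff(range(x$time))))
  invisible(x)
}

# ---- CSV log input/output ---------------------------------------------------
# Cane log header: t,strain,gx,gy,gz,ax,ay,az ; shank log header: t,gx.
# Plain decimal point, comma separator, one row per sample.

#' Read and write cane / shank sensor logs
#'
#' Logs are plain CSV, one row per sample.  The cane log header is
#' `t,strain,gx,gy,gz,ax,ay,az`; only `t` and `strain` are mandatory and
#' absent channels are zero-filled (and flagged in `meta$missing_channels`).
#' The shank log header is `t,gx`.
#'
#' @param path file path.
#' @param sample_rate optional sampling rate override; inferred from the time
#'   column otherwise.
#' @param meta named list merged into the recording's metadata.
#' @return `read_cane_log()` a [cane_recording()]; `read_shank_log()` a
#'   [shank_recording()].
#' @export
read_cane_log <- function(path, sample_rate = NULL, meta = list()) {
  df <- read_log_csv(path, required = c("t", "strain"))
  cane_recording(
    time = df$t, strain = df$strain,
    gyro_x = df$gx, gyro_y = df$gy, gyro_z = df$gz,
    accel_x = df$ax, accel_y = df$ay, accel_z = df$az,
    sample_rate = sample_rate, meta = meta
  )
}

#' @rdname read_cane_log
#' @export
read_shank_log <- function(path, sample_rate = NULL, meta = list()) {
  df <- read_log_csv(path, required = c("t", "gx"))
  shank_recording(time = df$t, gyro_ap = df$gx, sample_rate = sample_rate,
                  meta = meta)
}

read_log_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("malformed log %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) stop(sprintf("log %s has no data rows", path), call. = FALSE)
  if (nrow(df) >= 2L && any(diff(df$t) <= 0))
    stop(sprintf("log %s: time column not strictly increasing", path), call. = FALSE)
  df
}

#' @rdname read_cane_log
#' @param rec recording to write.
#' @export
write_cane_log <- function(rec, path) {
  stopifnot(inherits(rec, "cane_recording"))
  df <- data.frame(t = rec$time, strain = rec$strain,
                   gx = rec$gyro_x, gy = rec$gyro_y, gz = rec$gyro_z,
                   ax = rec$accel_x, ay = rec$accel_y, az = rec$accel_z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cane_log
#' @export
write_shank_log <- function(rec, path) {
  stopifnot(inherits(rec, "shank_recording"))
  utils::write.csv(data.frame(t = rec$time, gx = rec$gyro_ap), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
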