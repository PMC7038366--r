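#' Low-pass filter specification
#'
#' Preprocessing uses sixth-order Butterworth low-pass filters: 4 Hz for the
#' strain channel and 8 Hz for all gyroscope channels.  Filtering is
#' zero-phase (forward-backward) by default so that event timing carries no
#' group delay; a symmetric pulse keeps its apex sample exactly.
#'
#' @param order filter order (the order of the underlying Butterworth design;
#'   a zero-phase pass applies it twice).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param zero_phase apply forward-backward (`TRUE`, default) or single-pass
#'   causal filtering.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 6L, cutoff_hz, zero_phase = TRUE) {
  if (order < 1L) stop("filter order must be >= 1", call. = FALSE)
  if (cutoff_hz <= 0) stop("cutoff_hz must be > 0", call. = FALSE)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies the Butterworth design in `spec` to a uniformly sampled signal.
#' In zero-phase mode the signal is filtered forward and backward after odd
#' (point-reflection) edge padding, which removes group delay and suppresses
#' start-up transients; the effective amplitude response is the squared
#' magnitude of the single-pass design (so the cutoff attenuation is -6 dB).
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass <- function(x, sample_rate, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- sample_rate / 2
  if (spec$cutoff_hz >= nyq)
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 spec$cutoff_hz, nyq), call. = FALSE)
  if (length(x) < 3L * spec$order)
    stop("signal too short for the requested filter order", call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  if (!spec$zero_phase) {
    return(as.numeric(signal::filter(bf, x)))
  }
  # generous odd-reflection padding plus level anchoring: signal::filtfilt
  # starts its recursion from zero state, so the signal is shifted to start
  # near zero and long enough padding absorbs the remaining transient
  np <- min(length(x) - 1L,
            max(9L * spec$order, round(3 * sample_rate / spec$cutoff_hz)))
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - np)]
  xp <- c(pre, x, post)
  y <- signal::filtfilt(bf, xp - x[1L]) + x[1L]
  y[(np + 1L):(np + length(x))]
}

#' Baseline-correct a strain signal
#'
#' Raw strain-gauge output is an unsigned ADC level; the zero-crossing rules
#' used for event detection need a signed signal whose unloaded (cane in the
#' air) level sits just below zero.  The unloaded level is estimated as the
#' dominant mode of the sample distribution (the median of a symmetric band
#' around the density peak), which is unbiased under symmetric noise and
#' robust to the one-sided loading tail; it is then mapped to `floor_level`.
#'
#' With the default `floor_level = 0` the unloaded phase is centred on zero.
#' The pipeline ([preprocess()]) maps the floor to -2 counts instead, the
#' package's signed-strain convention, so that loading-phase onsets are clean
#' hysteresis zero-crossings.
#'
#' @param strain numeric strain signal (counts).
#' @param events_free_fraction fraction of lowest samples assumed free of
#'   loading events (default 0.3).
#' @param floor_level level (counts) the unloaded phase is mapped to.
#' @return Corrected signal; the shift applied is stored in
#'   `attr(, "baseline_shift")`.
#' @export
baseline_correct <- function(strain, events_free_fraction = 0.3,
                             floor_level = 0) {
  if (!length(strain)) stop("empty strain signal", call. = FALSE)
  rng <- diff(range(strain))
  if (rng < .Machine$double.eps * max(1, abs(strain[1L]))) {
    warning("degenerate (constant) strain signal; returning zeros")
    out <- numeric(length(strain))
    attr(out, "baseline_shift") <- -strain[1L]
    return(out)
  }
  fl <- floor_stats(strain, events_free_fraction)
  out <- strain - fl$level + floor_level
  attr(out, "baseline_shift") <- floor_level - fl$level
  out
}

# Locate the unloaded-phase level and its noise scale.  The unloaded level
# is the dominant mode of the sample distribution (the cane is off the
# ground much of the time, while loaded samples spread over hundreds of
# counts); the level is the median of a symmetric band around the density
# mode, which is robust to the one-sided loading tail and to filter-ringing
# excursions, and the noise scale is the MAD inside that band.
floor_stats <- function(x, events_free_fraction = 0.3) {
  rng <- diff(range(x))
  q <- stats::quantile(x, events_free_fraction, names = FALSE)
  tail_samples <- x[x <= q]
  noise0 <- stats::mad(tail_samples)
  if (noise0 == 0) noise0 <- max(rng * 1e-6, .Machine$double.eps)
  # density restricted to the lower half of the data, with a bandwidth fine
  # enough to resolve the floor peak against the loading tail
  lower <- x[x <= stats::quantile(x, max(events_free_fraction, 0.5), names = FALSE)]
  lrng <- diff(range(lower))
  bw <- max(2 * noise0, lrng * 0.005, .Machine$double.eps)
  dens <- stats::density(lower, bw = bw, n = 1024)
  pilot <- dens$x[which.max(dens$y)]
  if (pilot > q + 6 * noise0) pilot <- stats::median(tail_samples)
  in_band <- function(b) x[abs(x - pilot) <= b]
  noise <- stats::mad(in_band(max(5 * noise0, 2 * bw)))
  if (noise == 0) noise <- noise0
  floor_set <- in_band(max(5 * noise, 2 * bw))
  list(level = stats::median(floor_set), noise = noise)
}

#' Preprocess cane (and shank) recordings
#'
#' Applies the standard preprocessing chain: the strain channel is low-pass
#' filtered at `strain_cutoff_hz` (default 4 Hz) and baseline-corrected to
#' the signed-strain convention (`strain_floor` counts in the unloaded
#' phase); every gyroscope channel is low-pass filtered at `gyro_cutoff_hz`
#' (default 8 Hz).  All filters are sixth-order zero-phase Butterworth.
#' Applied specs are recorded in the recordings' metadata.
#'
#' @param cane a [cane_recording()].
#' @param shank an optional [shank_recording()]; pass `NULL` for cane-only
#'   trials.
#' @param strain_cutoff_hz,gyro_cutoff_hz filter cutoffs in Hz.
#' @param strain_floor unloaded-phase strain level after correction, counts.
#' @param events_free_fraction passed to [baseline_correct()].
#' @return A list with elements `cane` and `shank` (the latter `NULL` when no
#'   shank stream was supplied).
#' @export
preprocess <- function(cane, shank = NULL, strain_cutoff_hz = 4,
                       gyro_cutoff_hz = 8, strain_floor = -2,
                       events_free_fraction = 0.3) {
  stopifnot(inherits(cane, "cane_recording"))
  s_spec <- filter_spec(6L, strain_cutoff_hz)
  g_spec <- filter_spec(6L, gyro_cutoff_hz)
  cane$strain <- as.numeric(baseline_correct(
    lowpass(cane$strain, cane$sample_rate, s_spec),
    events_free_fraction = events_free_fraction, floor_level = strain_floor))
  for (ch in c("gyro_x", "gyro_y", "gyro_z"))
    cane[[ch]] <- lowpass(cane[[ch]], cane$sample_rate, g_spec)
  cane$meta$preprocessed <- TRUE
  cane$meta$strain_filter <- sprintf("butter order %d, %.3g Hz, zero-phase",
                                     s_spec$order, s_spec$cutoff_hz)
  cane$meta$gyro_filter <- sprintf("butter order %d, %.3g Hz, zero-phase",
                                   g_spec$order, g_spec$cutoff_hz)
  cane$meta$strain_floor <- strain_floor
  if (!is.null(shank)) {
    stopifnot(inherits(shank, "shank_recording"))
    shank$gyro_ap <- lowpass(shank$gyro_ap, shank$sample_rate, g_spec)
    shank$meta$preprocessed <- TRUE
    shank$meta$gyro_filter <- cane$meta$gyro_filter
  }
  list(cane = cane, shank = shank)
}
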