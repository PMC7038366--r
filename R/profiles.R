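#' Walking-condition profiles
#'
#' A `condition_profile` collects the per-stride parameter distributions that
#' define one walking condition for the synthetic-signal generator.  Each
#' distributed field is a `c(mean, sd)` pair; draws are truncated normals
#' (at 3 sd and at physical bounds).  The eleven built-in profiles returned
#' by [default_profiles()] carry the published condition summaries of the
#' instrumented-cane study for the eight gait features; fields the published
#' tables do not cover (phase durations, shank-stream analogues, and the
#' peak-velocity / peak-strain timing of the non-level conditions) take
#' documented defaults, scaled from the control condition.
#'
#' Field semantics (units in parentheses):
#' \describe{
#'   \item{stance_s}{cane loading-phase duration (s).}
#'   \item{swing_s}{cane swing-phase duration (s); informational - draws use
#'     `stance_s` and `swing_stance_ratio`.}
#'   \item{swing_stance_ratio}{swing/stance duration ratio (dimensionless).}
#'   \item{v_swing}{peak cane AP velocity in swing (deg/s).}
#'   \item{v_stance}{peak cane AP velocity in stance (deg/s).}
#'   \item{ps_offset_s}{time of the swing velocity peak after TC (s).}
#'   \item{strain_peak}{peak strain (ADC counts).}
#'   \item{strain_peak_offset_s}{time of the strain apex after IC (s).}
#'   \item{stride_length_m}{stride length (m).}
#'   \item{gpd_ic_lag_s}{lag of the cane-gyroscope post-swing local minimum
#'     after the strain IC zero-crossing (s); a positive lag produces a
#'     negative MSMF-GPD Difference-in-IC.}
#'   \item{cane_length_m}{cane length (m); the long/short conditions are
#'     +/- 2 inches (0.0508 m) from the control length.}
#'   \item{shank_v_swing}{peak shank AP velocity in swing (deg/s).}
#'   \item{shank_stance_s, shank_swing_s}{shank stance/swing durations (s);
#'     used as fractions of the stride period.}
#' }
#'
#' @param name condition label.
#' @param ... fields as described above; distributed fields as `c(mean, sd)`.
#' @return A `condition_profile` object (named list).
#' @export
condition_profile <- function(name, stance_s, swing_stance_ratio, v_swing,
                              v_stance, ps_offset_s, strain_peak,
                              strain_peak_offset_s, stride_length_m,
                              gpd_ic_lag_s, cane_length_m = 0.90,
                              shank_v_swing = NULL, shank_stance_s = NULL,
                              shank_swing_s = NULL) {
  ms <- function(x, what) {
    if (length(x) == 1L) x <- c(x, 0)
    if (length(x) != 2L || x[2L] < 0)
      stop(sprintf("%s must be c(mean, sd) with sd >= 0", what), call. = FALSE)
    c(mean = unname(x[1L]), sd = unname(x[2L]))
  }
  stance <- ms(stance_s, "stance_s")
  ratio <- ms(swing_stance_ratio, "swing_stance_ratio")
  vsw <- ms(v_swing, "v_swing")
  vst <- ms(v_stance, "v_stance")
  if (vsw["mean"] <= vst["mean"])
    stop("v_swing mean must exceed v_stance mean", call. = FALSE)
  swing <- c(mean = unname(stance["mean"] * ratio["mean"]),
             sd = unname(stance["sd"] * ratio["mean"]))
  ps <- ms(ps_offset_s, "ps_offset_s")
  if (ps["mean"] >= swing["mean"])
    stop("ps_offset_s mean must be below the swing duration", call. = FALSE)
  so <- ms(strain_peak_offset_s, "strain_peak_offset_s")
  if (so["mean"] >= stance["mean"])
    stop("strain_peak_offset_s mean must be below the stance duration", call. = FALSE)
  sl <- ms(stride_length_m, "stride_length_m")
  if (sl["mean"] < 0) stop("stride_length_m mean must be >= 0", call. = FALSE)
  cycle <- stance["mean"] + swing["mean"]
  if (is.null(shank_v_swing)) shank_v_swing <- 0.9 * vsw
  if (is.null(shank_stance_s)) shank_stance_s <- c(0.6 * cycle, 0.04)
  if (is.null(shank_swing_s)) shank_swing_s <- c(0.4 * cycle, 0.04)
  structure(list(
    name = name,
    stance_s = stance, swing_s = swing, swing_stance_ratio = ratio,
    v_swing = vsw, v_stance = vst, ps_offset_s = ps,
    strain_peak = ms(strain_peak, "strain_peak"),
    strain_peak_offset_s = so, stride_length_m = sl,
    gpd_ic_lag_s = ms(gpd_ic_lag_s, "gpd_ic_lag_s"),
    cane_length_m = cane_length_m,
    shank_v_swing = ms(shank_v_swing, "shank_v_swing"),
    shank_stance_s = ms(shank_stance_s, "shank_stance_s"),
    shank_swing_s = ms(shank_swing_s, "shank_swing_s")
  ), class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  cat(sprintf("<condition_profile> %s (cane %.3f m)\n", x$name, x$cane_length_m))
  for (f in setdiff(names(x), c("name", "cane_length_m")))
    cat(sprintf("  %-22s %8.4g +/- %.4g\n", f, x[[f]]["mean"], x[[f]]["sd"]))
  invisible(x)
}

#' Built-in profiles for the eleven walking conditions
#'
#' Returns the eleven condition profiles: control, plantarflexion,
#' dorsiflexion, uphill, downhill, upstairs, downstairs, fogged glasses,
#' eyes closed, long cane and short cane.  The distributed feature fields
#' (peak velocities, swing-stance ratio, peak strain, stride length and the
#' IC lag) carry the published per-condition mean/SD values; `gpd_ic_lag_s`
#' is the negated Difference-in-IC.  Phase durations are package defaults:
#' 0.65 s mean stance for level-ground conditions and 0.90 s for stair
#' conditions (stair walking is slower), with swing set by the published
#' swing-stance ratio.  Peak-timing fields missing from the published
#' summaries scale the control values by the condition's phase durations.
#'
#' @return Named list of [condition_profile()] objects.
#' @export
default_profiles <- function() {
  # ps/strain timing defaults for conditions whose tables omit them:
  # scale the control 0.258 s (after TC) and 0.3619 s (after IC) by the
  # condition's swing / stance duration relative to control.
  ctl_stance <- 0.65
  ps_scaled <- function(stance, ratio)
    c(0.258, 0.058) * (stance * ratio) / (ctl_stance * 1.0)
  so_scaled <- function(stance) c(0.3619, 0.0732) * stance / ctl_stance
  p <- list()
  p$control <- condition_profile("control",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(1.0, 0.2),
    v_swing = c(246.5, 55.5), v_stance = c(156.4, 33.3),
    ps_offset_s = c(0.258, 0.058),
    strain_peak = c(110.6, 57.7), strain_peak_offset_s = c(0.3619, 0.0732),
    stride_length_m = c(1.1, 0.4), gpd_ic_lag_s = c(0.0126, 0.0066))
  p$plantarflexion <- condition_profile("plantarflexion",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(0.9, 0.7),
    v_swing = c(228.3, 73.8), v_stance = c(148.8, 28.5),
    ps_offset_s = c(0.2173, 0.0524),
    strain_peak = c(179.3, 93.3), strain_peak_offset_s = c(0.4121, 0.0999),
    stride_length_m = c(0.9, 0.3), gpd_ic_lag_s = c(0.0202, 0.0116))
  p$dorsiflexion <- condition_profile("dorsiflexion",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(0.8, 0.2),
    v_swing = c(204.9, 61.6), v_stance = c(124.6, 23.3),
    ps_offset_s = c(0.2048, 0.0359),
    strain_peak = c(188, 83), strain_peak_offset_s = c(0.419, 0.080),
    stride_length_m = c(0.8, 0.3), gpd_ic_lag_s = c(0.025, 0.0141))
  p$uphill <- condition_profile("uphill",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(1.0, 0.5),
    v_swing = c(270, 73), v_stance = c(166.3, 27.5),
    ps_offset_s = ps_scaled(0.65, 1.0),
    strain_peak = c(159.7, 74.5), strain_peak_offset_s = so_scaled(0.65),
    stride_length_m = c(1.1, 0.4), gpd_ic_lag_s = c(0.0193, 0.0128))
  p$downhill <- condition_profile("downhill",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(1.0, 0.3),
    v_swing = c(268.1, 76.2), v_stance = c(189.6, 33.5),
    ps_offset_s = ps_scaled(0.65, 1.0),
    strain_peak = c(135.7, 67.3), strain_peak_offset_s = so_scaled(0.65),
    stride_length_m = c(1.2, 0.4), gpd_ic_lag_s = c(0.0125, 0.0068))
  p$upstairs <- condition_profile("upstairs",
    stance_s = c(0.90, 0.08), swing_stance_ratio = c(0.7, 0.2),
    v_swing = c(68.3, 21.3), v_stance = c(37.4, 8.8),
    ps_offset_s = ps_scaled(0.90, 0.7),
    strain_peak = c(201.7, 122.9), strain_peak_offset_s = so_scaled(0.90),
    stride_length_m = c(0.3, 0.2), gpd_ic_lag_s = c(0.0787, 0.0297))
  p$downstairs <- condition_profile("downstairs",
    stance_s = c(0.90, 0.08), swing_stance_ratio = c(0.7, 0.3),
    v_swing = c(79.6, 26.4), v_stance = c(38.3, 14.2),
    ps_offset_s = ps_scaled(0.90, 0.7),
    strain_peak = c(179.8, 104.7), strain_peak_offset_s = so_scaled(0.90),
    stride_length_m = c(0.2, 0.1), gpd_ic_lag_s = c(0.0633, 0.0274))
  p$fogged_glasses <- condition_profile("fogged_glasses",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(0.9, 0.2),
    v_swing = c(243.5, 63.6), v_stance = c(147.4, 24.9),
    ps_offset_s = ps_scaled(0.65, 0.9),
    strain_peak = c(141.9, 80.9), strain_peak_offset_s = so_scaled(0.65),
    stride_length_m = c(1.1, 0.3), gpd_ic_lag_s = c(0.0193, 0.0105))
  p$eyes_closed <- condition_profile("eyes_closed",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(0.8, 0.3),
    v_swing = c(194.8, 54.2), v_stance = c(104.1, 23.3),
    ps_offset_s = ps_scaled(0.65, 0.8),
    strain_peak = c(147.2, 76.3), strain_peak_offset_s = so_scaled(0.65),
    stride_length_m = c(0.8, 0.3), gpd_ic_lag_s = c(0.0284, 0.0159))
  p$long_cane <- condition_profile("long_cane",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(0.9, 0.3),
    v_swing = c(243.3, 61.7), v_stance = c(146.9, 27.7),
    ps_offset_s = ps_scaled(0.65, 0.9),
    strain_peak = c(143.4, 77.7), strain_peak_offset_s = so_scaled(0.65),
    stride_length_m = c(1.3, 0.4), gpd_ic_lag_s = c(0.0216, 0.0102),
    cane_length_m = 0.90 + 0.0508)
  p$short_cane <- condition_profile("short_cane",
    stance_s = c(0.65, 0.06), swing_stance_ratio = c(1.0, 0.3),
    v_swing = c(246.9, 65.4), v_stance = c(153.2, 28.3),
    ps_offset_s = ps_scaled(0.65, 1.0),
    strain_peak = c(167, 85.1), strain_peak_offset_s = so_scaled(0.65),
    stride_length_m = c(0.8, 0.3), gpd_ic_lag_s = c(0.0233, 0.013),
    cane_length_m = 0.90 - 0.0508)
  p
}
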