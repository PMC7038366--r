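# Synthetic trial generator: per-stride waveform model with exact ground truth.
#
# Signal model (continuous time, one stride spanning [IC, EC]):
#  * strain: quartic-sine (sin^4) rise/fall bump over the loading phase with
#    apex `strain_peak` at IC + strain_peak_offset, resting at -eps elsewhere;
#    the bump knots are placed so the hysteresis zero-crossings fall exactly
#    at IC (positive) and TC (negative).
#  * cane AP gyro: a sin^2 stance lobe peaking at v_stance, then a swing
#    complex: a sine-power rise to v_swing at PS = TC + ps_offset, a
#    cosine-power fall (optionally preceded by a gently tilted plateau for
#    long strides) to zero, and a compact symmetric dip of depth -d whose
#    minimum sits at EC + gpd_ic_lag.  The fall exponent, rise exponent,
#    plateau length and, in the extreme, an overall duration stretch are
#    solved so that the trapezoidal integral of the swing-phase velocity over
#    (TC, EC] equals the pendulum sweep angle
#    theta = 2 asin(stride_length / (2 cane_length)).
#  * shank AP gyro: symmetric negative dips at each stride boundary (IC) and
#    at the shank TC, a swing bump peaking at shank_v_swing between them, and
#    a small stance lobe (0.2 x swing peak).
#
# Emitted channels are band-limited with the package's own zero-phase filters
# (4 Hz strain / 8 Hz gyro); the strain knots are pre-compensated so that the
# analysis pipeline's filtered zero-crossings and apex land on the ground
# truth times.  White noise at the configured SDs is added last.

STRAIN_EPS <- 2          # swing-phase strain level, counts below zero
V_CORR <- 0.8            # swing/stance peak-velocity draw correlation
DIP_FRACTION <- 0.25     # gyro dip depth as a fraction of v_swing
GYRO_DIP_W <- 0.10       # half-width (s) of the cane end-of-swing dip
PLATEAU_TILT <- 0.12     # fractional droop over a swing plateau (keeps the
                         # velocity maximum unique at PS)
SHANK_DIP_W <- 0.09      # half-width (s) of shank boundary/TC dips
SHANK_STANCE_AMP <- 0.2  # shank stance lobe amplitude, fraction of swing peak

#' Study configuration
#'
#' Bundles the design of a synthetic study: cohort size, strides per trial,
#' conditions, sampling rates, noise levels, and how the published pooled
#' per-condition variance is split between a between-participant and a
#' within-participant (stride-to-stride) level.
#'
#' @param n_participants number of participants (default 30).
#' @param strides_per_trial strides generated per trial (default 40).
#' @param conditions character vector of profile names (see
#'   [default_profiles()]).
#' @param seed integer seed; fixing it makes every generated byte
#'   reproducible.
#' @param fs_cane,fs_shank sampling rates in Hz (defaults 231 and 100).
#' @param noise_sd_strain,noise_sd_gyro white-noise SDs added to the emitted
#'   channels (counts, deg/s).
#' @param between_participant_sd_scale share of each field's variance
#'   allocated to the between-participant level (0..1, default 0.5).
#' @return A `study_config` object.
#' @export
study_config <- function(n_participants = 30L, strides_per_trial = 40L,
                         conditions = names(default_profiles()), seed = 1L,
                         fs_cane = 231, fs_shank = 100,
                         noise_sd_strain = 1, noise_sd_gyro = 1,
                         between_participant_sd_scale = 0.5) {
  stopifnot(n_participants >= 1L, strides_per_trial >= 1L,
            length(conditions) >= 1L, fs_cane > 0, fs_shank > 0,
            noise_sd_strain >= 0, noise_sd_gyro >= 0,
            between_participant_sd_scale >= 0,
            between_participant_sd_scale <= 1)
  structure(list(
    n_participants = as.integer(n_participants),
    strides_per_trial = as.integer(strides_per_trial),
    conditions = conditions, seed = as.integer(seed),
    fs_cane = fs_cane, fs_shank = fs_shank,
    noise_sd_strain = noise_sd_strain, noise_sd_gyro = noise_sd_gyro,
    between_participant_sd_scale = between_participant_sd_scale
  ), class = "study_config")
}

#' @rdname study_config
#' @param path YAML file path (flat key-value mapping; `conditions` is a
#'   comma-separated string).
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  flat <- cfg
  flat$conditions <- paste(cfg$conditions, collapse = ",")
  yaml::write_yaml(unclass(flat), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$conditions <- strsplit(raw$conditions, ",", fixed = TRUE)[[1L]]
  do.call(study_config, raw)
}

#' @rdname study_config
#' @param cfg a `study_config`.
#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d participants x %d conditions x %d strides, seed %d\n",
              x$n_participants, length(x$conditions), x$strides_per_trial, x$seed))
  invisible(x)
}

# truncated standard normal draws (+/- 3 sd) via inverse CDF, seed-friendly
trunc_z <- function(n) {
  lo <- stats::pnorm(-3)
  stats::qnorm(stats::runif(n, lo, 1 - lo))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# minimum strain fall duration (apex to TC, seconds): heavier loading peaks
# release over a longer interval, which also keeps the band-limited release
# free of ringing large enough to disturb the zero-crossing logic
ramp_need <- function(peak) 0.16 + 0.05 * pmax(0, log(peak / 180))

# fields that receive a participant-level shift (z-score units)
SHIFT_FIELDS <- c("stance_s", "swing_stance_ratio", "v_swing", "v_stance",
                  "ps_offset_s", "strain_peak", "strain_peak_offset_s",
                  "stride_length_m", "gpd_ic_lag_s", "shank_v_swing")

#' Participant-level mean shifts
#'
#' Draws one z-score per participant and profile field.  The same shift
#' record is reused for all of a participant's conditions, which induces the
#' within-subject correlation a repeated-measures analysis relies on.  The
#' swing- and stance-velocity shifts are correlated (r = 0.8): participants
#' who swing the cane fast also move it fast in stance.
#'
#' @param cfg a [study_config()].
#' @return Matrix `n_participants x length(fields)` of z-scores.
#' @export
participant_shifts <- function(cfg) {
  n <- cfg$n_participants
  z <- matrix(trunc_z(n * length(SHIFT_FIELDS)), nrow = n,
              dimnames = list(NULL, SHIFT_FIELDS))
  z[, "v_stance"] <- clamp(V_CORR * z[, "v_swing"] +
                             sqrt(1 - V_CORR^2) * z[, "v_stance"], -3, 3)
  # centre each field across the cohort: the simulated cohort reproduces the
  # published condition means exactly instead of drifting around them, while
  # stride-to-stride variability stays independent
  if (n > 1L) z <- sweep(z, 2L, colMeans(z))
  z[, "shank_v_swing"] <- z[, "v_swing"]
  z
}

#' Draw per-stride generator parameters
#'
#' Draws `n` stride parameter records from a condition profile.  Each field
#' is a truncated normal: mean + sd * (sqrt(s) z_participant +
#' sqrt(1-s) z_stride) with s = `between_participant_sd_scale`, z truncated
#' at +/-3.  Swing and stance peak velocities are correlated (r = 0.8) at
#' both levels.  Draws are then clamped to physical bounds (positive
#' durations, apex offsets inside their phase, v_stance < v_swing,
#' stride length inside the pendulum's reach).
#'
#' @param profile a [condition_profile()].
#' @param n number of strides.
#' @param shift named participant z-score vector (see [participant_shifts()]);
#'   zeros when omitted.
#' @param sd_scale between-participant share of variance.
#' @return data.frame with one row per stride.
#' @export
draw_stride_params <- function(profile, n, shift = NULL, sd_scale = 0.5) {
  if (is.null(shift)) shift <- stats::setNames(numeric(length(SHIFT_FIELDS)),
                                               SHIFT_FIELDS)
  sb <- sqrt(sd_scale); sw <- sqrt(1 - sd_scale)
  dr <- function(field, zs) {
    mu <- profile[[field]]["mean"]; sd <- profile[[field]]["sd"]
    unname(mu + sd * (sb * shift[[field]] + sw * zs))
  }
  z_vsw <- trunc_z(n)
  z_vst <- clamp(V_CORR * z_vsw + sqrt(1 - V_CORR^2) * trunc_z(n), -3, 3)
  L <- profile$cane_length_m
  stance <- pmax(dr("stance_s", trunc_z(n)), 0.35)
  ratio <- pmax(dr("swing_stance_ratio", trunc_z(n)), 0.25)
  swing <- ratio * stance
  short <- swing < 0.35
  swing[short] <- 0.35
  ratio <- swing / stance
  v_swing <- pmax(dr("v_swing", z_vsw), 15)
  v_stance <- clamp(dr("v_stance", z_vst), 3, 0.95 * v_swing)
  lag <- clamp(dr("gpd_ic_lag_s", trunc_z(n)), -0.05, pmin(0.25 * stance, 0.2))
  ps <- clamp(dr("ps_offset_s", trunc_z(n)), 0.08,
              pmin(0.75 * swing, swing + lag - GYRO_DIP_W - 0.06))
  strain_peak <- pmax(dr("strain_peak", trunc_z(n)), 15)
  data.frame(
    stance = stance, swing = swing, ratio = ratio,
    v_swing = v_swing, v_stance = v_stance, ps_offset = ps,
    strain_peak = strain_peak,
    strain_off = clamp(dr("strain_peak_offset_s", trunc_z(n)), 0.08,
                       pmin(0.8 * stance, stance - ramp_need(strain_peak))),
    stride_len = clamp(dr("stride_length_m", trunc_z(n)), 0, 1.96 * L),
    lag = lag,
    d = pmax(DIP_FRACTION * v_swing, 8),
    shank_v = pmax(dr("shank_v_swing", trunc_z(n)), 10),
    shank_fr = clamp(stats::rnorm(n,
      profile$shank_stance_s["mean"] /
        (profile$shank_stance_s["mean"] + profile$shank_swing_s["mean"]),
      0.03), 0.45, 0.75)
  )
}

# ---- waveform pieces --------------------------------------------------------

# strain bump contribution with zero-crossings pinned at (ic, tc); adds to a
# baseline of -eps.  Knots may be pre-compensated copies of the truth times.
strain_bump_add <- function(x, t, ic, tc, apex, peak, eps = STRAIN_EPS) {
  delta <- eps / (peak + eps)
  frac <- (2 / pi) * asin(delta^0.25)
  rr <- (apex - ic) / (1 - frac); t0 <- apex - rr
  rf <- (tc - apex) / (1 - frac); t1 <- apex + rf
  i <- which(t >= t0 & t <= apex)
  x[i] <- x[i] + (peak + eps) * sin(pi / 2 * (t[i] - t0) / rr)^4
  i <- which(t > apex & t <= t1)
  x[i] <- x[i] + (peak + eps) * sin(pi / 2 * (t1 - t[i]) / rf)^4
  x
}

# cane gyro swing complex for one stride, evaluated at times t (absolute).
# Quarter-sine rise to v at PS = tc + ps_off, cosine-power fall (exponent p
# sets the area) reaching zero just before the end-of-swing dip, then a
# compact symmetric cos^2 dip of half-width GYRO_DIP_W and depth d whose
# minimum sits exactly at ec + lag (the GPD initial-contact landmark).
# Returns the contribution (baseline 0).
gyro_swing_eval <- function(t, tc, ec, v, ps_off, lag, d, p, r, lam = 0) {
  g <- numeric(length(t))
  PS <- tc + ps_off
  tmin <- ec + lag
  Th <- tmin - GYRO_DIP_W - PS      # fall duration; > 0 by draw clamping
  i <- which(t > tc & t <= PS)
  if (length(i)) g[i] <- v * sin(pi / 2 * (t[i] - tc) / ps_off)^(2 * r)
  if (lam > 0) {
    i <- which(t > PS & t <= PS + lam)
    if (length(i)) g[i] <- v * (1 - PLATEAU_TILT * (t[i] - PS) / lam)
    vtop <- v * (1 - PLATEAU_TILT)
    i <- which(t > PS + lam & t <= PS + Th)
    if (length(i)) g[i] <- vtop * ((1 + cos(pi * (t[i] - PS - lam) / (Th - lam))) / 2)^p
  } else {
    i <- which(t > PS & t <= PS + Th)
    if (length(i)) g[i] <- v * ((1 + cos(pi * (t[i] - PS) / Th)) / 2)^p
  }
  i <- which(abs(t - tmin) <= GYRO_DIP_W)
  if (length(i)) g[i] <- g[i] - d * cos(pi / 2 * (t[i] - tmin) / GYRO_DIP_W)^2
  g
}

trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((t[-1L] - t[-n]) * (y[-1L] + y[-n]) / 2)
}

# swing integral (degrees) of the construction over samples in (tc, ec]
swing_integral_grid <- function(fs, tc, ec, v, ps_off, lag, d, p, r, lam = 0) {
  j <- seq.int(floor(tc * fs + 1e-9) + 1L, floor(ec * fs + 1e-9))
  tt <- j / fs
  trapz(tt, gyro_swing_eval(tt, tc, ec, v, ps_off, lag, d, p, r, lam))
}

# Solve the swing-shape free parameters (fall exponent p, rise exponent r,
# duration stretch) so the sampled swing integral over (TC, EC] equals
# theta_deg.  `ic` anchors the stride on the absolute sample grid; stance and
# swing are durations.  A stretch > 1 lengthens both phases (preserving the
# swing-stance ratio) when the sweep cannot fit in the drawn cycle.
solve_swing_shape <- function(fs, ic, stance, swing, v, ps_off, lag, d,
                              theta_deg, stride_id = NA,
                              infeasible = c("error", "clamp")) {
  infeasible <- match.arg(infeasible)
  G <- function(p, r, lam = 0, st = stance, sw = swing, dd = d)
    swing_integral_grid(fs, ic + st, ic + st + sw, v, ps_off, lag, dd, p, r, lam)
  lam_max <- function(sw = swing) (sw + lag - ps_off - GYRO_DIP_W) - 0.06
  # p >= 1 keeps the fall's end slope zero (no corner, no filter undershoot
  # into the dip); extra area for long strides comes from flattening the
  # rise top (r < 0.5), then from a tilted plateau after PS, and only in the
  # extreme from stretching the cycle
  p_lo <- 1; p_hi <- 40; r_def <- 0.5; r_min <- 0.25; r_hi <- 30
  stretch <- 1; lam <- 0
  cap_top <- function() {
    lm <- lam_max()
    if (lm >= 0.06) G(p_lo, r_min, lm) else G(p_lo, r_min)
  }
  if (theta_deg > cap_top()) {
    # keep stretched cycles within stride-duration plausibility
    f_cap <- max(1, min(4, 2.6 / (stance + swing)))
    h <- function(f) {
      lm <- lam_max(swing * f)
      G(p_lo, r_min, if (lm >= 0.06) lm else 0, stance * f, swing * f) -
        theta_deg * 1.02
    }
    if (h(f_cap) < 0) {
      if (infeasible == "error")
        stop(sprintf("sweep-angle constraint unsatisfiable for stride %s: theta %.1f deg with v_swing %.1f deg/s",
                     stride_id, theta_deg, v), call. = FALSE)
      # physical bound: this walker cannot sweep that far at that speed;
      # realize the largest achievable sweep instead
      stretch <- f_cap
      stance <- stance * stretch; swing <- swing * stretch
      lam <- lam_max()
      if (lam < 0.06) lam <- 0
      theta_achieved <- G(p_lo, r_min, lam)
      return(list(p = p_lo, r = r_min, lam = lam, d = d, stretch = stretch,
                  stance = stance, swing = swing, theta = theta_achieved))
    }
    stretch <- stats::uniroot(h, c(1, f_cap), tol = 1e-6)$root
    stance <- stance * stretch; swing <- swing * stretch
  }
  p <- p_lo; r <- r_def
  if (theta_deg > G(p_lo, r_min) && lam_max() >= 0.06) {
    # long stride: flat rise plus plateau, length solved for the area
    r <- r_min
    lam <- stats::uniroot(function(ll) G(p_lo, r_min, ll) - theta_deg,
                          c(0.02, lam_max()), tol = 1e-9, extendInt = "upX")$root
  } else if (theta_deg > G(p_lo, r_def)) {
    # flatten the rise top at p = 1 for extra area
    r <- tryCatch(stats::uniroot(function(rr) G(p_lo, rr) - theta_deg,
                                 c(r_min, r_def), tol = 1e-9)$root,
                  error = function(e) r_min)
  } else if (theta_deg >= G(p_hi, r_def)) {
    p <- stats::uniroot(function(pp) G(pp, r_def) - theta_deg,
                        c(p_lo, p_hi), tol = 1e-9)$root
  } else if (theta_deg >= G(p_hi, 2000)) {
    # short stride: keep the fall moderate and sharpen the rise instead
    p <- p_hi
    r <- stats::uniroot(function(rr) G(p_hi, rr) - theta_deg,
                        c(r_def, 2000), tol = 1e-9)$root
  } else if (theta_deg >= G(1000, 2000)) {
    # very short stride: sharpen the fall into a narrow spike as well
    r <- 2000
    p <- stats::uniroot(function(pp) G(pp, 2000) - theta_deg,
                        c(p_hi, 1000), tol = 1e-9)$root
  } else {
    # near-zero sweep: the end-of-swing dip's negative area balances the
    # residual spike areas
    p <- 1000; r <- 2000
    hd <- function(dd) G(p, r, dd = dd) - theta_deg
    if (hd(4 * d) < 0) {
      # deepen the dip (an internal landmark, not a reported feature)
      d <- stats::uniroot(hd, c(d, 4 * d), tol = 1e-9)$root
    }             # else: achieved sweep floor; stride length clamps
  }
  theta_achieved <- G(p, r, lam)
  list(p = p, r = r, lam = lam, d = d, stretch = stretch, stance = stance,
       swing = swing, theta = theta_achieved)
}

#' Synthesize one stride
#'
#' Realizes the generator's signal model for a single stride: the strain
#' loading bump, the cane AP gyro stance lobe and swing complex (with the
#' fall shape solved so the swing-phase sweep integral matches the pendulum
#' angle of the drawn stride length), and the shank AP gyro pattern.  The
#' returned waveforms are the ideal (unfiltered, noise-free) model sampled at
#' `fs` / `fs_shank`; [generate_trial()] additionally band-limits, adds
#' noise, and pre-compensates the strain knots.
#'
#' @param profile a [condition_profile()].
#' @param draw one-row data.frame of stride parameters
#'   ([draw_stride_params()]); profile means when omitted.
#' @param fs,fs_shank sampling rates, Hz.
#' @return List with `t`, `strain`, `gyro_ap`, `t_shank`, `shank_gyro_ap`,
#'   `events` (IC/TC/PS/EC times for both streams, stride-local clock),
#'   and `params` (the effective draw incl. solved shape parameters).
#' @export
synth_stride <- function(profile, draw = NULL, fs = 231, fs_shank = 100) {
  if (is.null(draw)) {
    m <- function(f) unname(profile[[f]]["mean"])
    draw <- data.frame(
      stance = m("stance_s"),
      swing = m("stance_s") * m("swing_stance_ratio"),
      ratio = m("swing_stance_ratio"),
      v_swing = m("v_swing"), v_stance = m("v_stance"),
      ps_offset = m("ps_offset_s"),
      strain_peak = m("strain_peak"), strain_off = m("strain_peak_offset_s"),
      stride_len = m("stride_length_m"), lag = m("gpd_ic_lag_s"),
      d = max(DIP_FRACTION * m("v_swing"), 8),
      shank_v = m("shank_v_swing"),
      shank_fr = m("shank_stance_s") / (m("shank_stance_s") + m("shank_swing_s"))
    )
  }
  L <- profile$cane_length_m
  theta <- 2 * asin(clamp(draw$stride_len / (2 * L), 0, 1)) * 180 / pi
  lead <- 0.4; tail <- 0.6
  shp <- solve_swing_shape(fs, lead, draw$stance, draw$swing, draw$v_swing,
                           draw$ps_offset, draw$lag, draw$d, theta,
                           stride_id = "1")
  stance <- shp$stance; swing <- shp$swing
  ic <- lead; tc <- ic + stance; ec <- tc + swing; ps <- tc + draw$ps_offset
  t <- seq(0, ec + tail, by = 1 / fs)
  strain <- strain_bump_add(numeric(length(t)), t, ic, tc,
                            ic + draw$strain_off, draw$strain_peak) - STRAIN_EPS
  draw$d <- shp$d
  g <- gyro_swing_eval(t, tc, ec, draw$v_swing, draw$ps_offset, draw$lag,
                       draw$d, shp$p, shp$r, shp$lam)
  a <- ic + 0.06; b <- tc - 0.02
  i <- which(t >= a & t <= b)
  g[i] <- g[i] + draw$v_stance * sin(pi * (t[i] - a) / (b - a))^2
  t_sh <- seq(0, ec + tail, by = 1 / fs_shank)
  sh <- shank_eval(t_sh, boundaries = c(ic, ec),
                   tcs = ic + draw$shank_fr * (ec - ic),
                   pss = NULL, v = draw$shank_v)
  ev <- list(
    cane = c(ic = ic, tc = tc, ps = ps, ec = ec),
    shank = c(ic = ic, tc = ic + draw$shank_fr * (ec - ic),
              ps = shank_ps_time(ic, ec, draw$shank_fr), ec = ec)
  )
  params <- cbind(draw, p = shp$p, r = shp$r, lam = shp$lam,
                  stretch = shp$stretch,
                  stance_eff = stance, swing_eff = swing,
                  theta_deg = shp$theta,
                  stride_len_achieved = 2 * L * sin(clamp(shp$theta, 0, 180) / 2 * pi / 180))
  list(t = t, strain = strain, gyro_ap = g, t_shank = t_sh,
       shank_gyro_ap = sh, events = ev, params = params)
}

# shank PS sits at the midpoint of the swing bump support, so the generated
# bump is symmetric about it and filtering leaves the apex in place
shank_ps_time <- function(ic, ec, fr) {
  tcs <- ic + fr * (ec - ic)
  (tcs + SHANK_DIP_W + ec - SHANK_DIP_W) / 2
}

# shank AP gyro: boundary dips, TC dips, swing bumps, small stance lobes.
# boundaries: vector of stride-boundary (IC) walk times, length n+1.
# tcs: per-stride shank TC times; v: per-stride swing peak amplitudes.
shank_eval <- function(t, boundaries, tcs, pss = NULL, v) {
  g <- numeric(length(t))
  w <- SHANK_DIP_W
  nb <- length(boundaries)
  nstr <- nb - 1L
  v <- rep_len(v, max(nstr, 1L))
  # boundary (IC/EC) valleys are deeper than TC valleys so the two are
  # distinguishable in every inter-peak interval
  dcap <- 0.45 * max(v)
  for (bi in seq_len(nb)) {   # boundary dips (EC/IC)
    i <- which(abs(t - boundaries[bi]) <= w)
    if (length(i)) g[i] <- g[i] - dcap * cos(pi / 2 * (t[i] - boundaries[bi]) / w)^2
  }
  for (k in seq_len(nstr)) {
    b0 <- boundaries[k]; b1 <- boundaries[k + 1L]; tck <- tcs[k]; vk <- v[k]
    dk <- 0.25 * vk
    i <- which(abs(t - tck) <= w)  # TC dip
    if (length(i)) g[i] <- g[i] - dk * cos(pi / 2 * (t[i] - tck) / w)^2
    # symmetric swing bump spanning (tck + w, b1 - w), apex at the midpoint
    i <- which(t > tck + w & t < b1 - w)
    if (length(i)) g[i] <- g[i] + vk * sin(pi * (t[i] - tck - w) / (b1 - tck - 2 * w))^2
    a <- b0 + w + 0.04; b <- tck - w - 0.02  # stance lobe
    if (b - a > 0.08) {
      i <- which(t >= a & t <= b)
      if (length(i)) g[i] <- g[i] + SHANK_STANCE_AMP * vk * sin(pi * (t[i] - a) / (b - a))^2
    }
  }
  g
}

# measure strain landmarks (crossings by linear interpolation, apex by
# quadratic interpolation) near their expected times on a noise-free signal
measure_strain_events <- function(x, t, ic, tc, apex, win = 0.12) {
  fs <- 1 / (t[2L] - t[1L])
  pos_cross <- function(t0) {
    i0 <- max(1L, floor((t0 - win) * fs)); i1 <- min(length(x) - 1L, ceiling((t0 + win) * fs))
    idx <- i0:i1
    k <- idx[x[idx] < 0 & x[idx + 1L] >= 0]
    if (!length(k)) return(NA_real_)
    k <- k[which.min(abs(t[k] - t0))]
    t[k] + (0 - x[k]) / (x[k + 1L] - x[k]) / fs
  }
  neg_cross <- function(t0) {
    i0 <- max(1L, floor((t0 - win) * fs)); i1 <- min(length(x) - 1L, ceiling((t0 + win) * fs))
    idx <- i0:i1
    k <- idx[x[idx] >= 0 & x[idx + 1L] < 0]
    if (!length(k)) return(NA_real_)
    k <- k[which.min(abs(t[k] - t0))]
    t[k] + (0 - x[k]) / (x[k + 1L] - x[k]) / fs
  }
  apex_m <- function(t0) {
    i0 <- max(2L, floor((t0 - win) * fs)); i1 <- min(length(x) - 1L, ceiling((t0 + win) * fs))
    idx <- i0:i1
    k <- idx[which.max(x[idx])]
    aa <- x[k - 1L]; bb <- x[k]; cc <- x[k + 1L]
    den <- aa - 2 * bb + cc
    dt <- if (den != 0) 0.5 * (aa - cc) / den / fs else 0
    pk <- bb - if (den != 0) 0.125 * (aa - cc)^2 / den else 0
    c(t[k] + dt, pk)
  }
  n <- length(ic)
  out <- matrix(NA_real_, n, 4L,
                dimnames = list(NULL, c("ic", "tc", "apex", "peak")))
  for (k in seq_len(n)) {
    out[k, "ic"] <- pos_cross(ic[k])
    out[k, "tc"] <- neg_cross(tc[k])
    am <- apex_m(apex[k])
    out[k, "apex"] <- am[1L]; out[k, "peak"] <- am[2L]
  }
  out
}

#' Generate one synthetic walking trial
#'
#' Concatenates `cfg$strides_per_trial` strides drawn from the
#' (participant-shifted) profile distributions, prepends and appends quiet
#' standing (cane held off the ground, strain at its unloaded floor), adds a
#' terminal cane plant so the last stride's end-of-contact crossing exists,
#' band-limits all channels with the package's zero-phase filters
#' (pre-compensating the strain knots so pipeline-measured events land on
#' the truth times), adds white noise, and samples the cane at `fs_cane` and
#' the shank at `fs_shank`.  The shank stream's clock starts `stream_shift`
#' seconds into the cane clock; the shift is recorded in the truth.
#'
#' @param profile a [condition_profile()].
#' @param cfg a [study_config()].
#' @param shift named participant z-score vector; zeros when `NULL`.
#' @param seed integer seed for this trial.
#' @param stream_shift cane-minus-shank clock offset in seconds; drawn
#'   uniformly from (-1, 1) when `NULL`.
#' @param meta extra labels stored in the recordings' metadata.
#' @return List with `cane` ([cane_recording()]), `shank`
#'   ([shank_recording()]), and `truth` (list: `events` data.frame with
#'   per-stride IC/TC/PS/EC times for both streams, `params` data.frame of
#'   effective per-stride draws, `start_offset`, `seed`).
#' @export
generate_trial <- function(profile, cfg, shift = NULL, seed = 1L,
                           stream_shift = NULL, meta = list()) {
  set.seed(seed)
  n <- cfg$strides_per_trial
  fs <- cfg$fs_cane
  if (is.null(stream_shift)) stream_shift <- stats::runif(1, -1, 1)
  dr <- draw_stride_params(profile, n + 1L, shift,
                           cfg$between_participant_sd_scale)
  dr$p <- NA_real_; dr$r <- NA_real_; dr$lam <- 0; dr$stretch <- 1
  dr$theta_deg <- NA_real_; dr$stride_len_achieved <- NA_real_
  L <- profile$cane_length_m

  # --- solve per-stride geometry sequentially (on the absolute sample grid)
  lead <- 2.5
  ic <- numeric(n + 1L); tc <- numeric(n + 1L); ec <- numeric(n)
  ps <- numeric(n)
  ic[1L] <- lead
  for (k in seq_len(n)) {
    theta <- 2 * asin(clamp(dr$stride_len[k] / (2 * L), 0, 1)) * 180 / pi
    shp <- solve_swing_shape(fs, ic[k], dr$stance[k], dr$swing[k],
                             dr$v_swing[k], dr$ps_offset[k],
                             dr$lag[k], dr$d[k], theta, stride_id = k,
                             infeasible = "clamp")
    dr$stance[k] <- shp$stance; dr$swing[k] <- shp$swing
    dr$ratio[k] <- dr$swing[k] / dr$stance[k]
    dr$p[k] <- shp$p; dr$r[k] <- shp$r; dr$lam[k] <- shp$lam
    dr$d[k] <- shp$d; dr$stretch[k] <- shp$stretch
    dr$theta_deg[k] <- shp$theta
    dr$stride_len_achieved[k] <-
      2 * L * sin(clamp(shp$theta, 0, 180) / 2 * pi / 180)
    dr$strain_off[k] <- min(dr$strain_off[k], 0.8 * dr$stance[k],
                            dr$stance[k] - ramp_need(dr$strain_peak[k]))
    tc[k] <- ic[k] + dr$stance[k]
    ec[k] <- tc[k] + dr$swing[k]
    ps[k] <- tc[k] + dr$ps_offset[k]
    ic[k + 1L] <- ec[k]
  }
  k <- n + 1L  # terminal plant: gentle fall so no spurious crossing follows
  tc[k] <- ic[k] + dr$stance[k]
  dr$strain_off[k] <- min(dr$strain_off[k], 0.5 * dr$stance[k])
  t_end <- tc[n + 1L] + 2.5
  t <- seq(0, t_end, by = 1 / fs)

  # --- strain with knot pre-compensation against the double filter pass
  apex <- ic + dr$strain_off
  k_ic <- ic; k_tc <- tc; k_apex <- apex; k_peak <- dr$strain_peak
  s_spec <- filter_spec(6L, 4)
  for (iter in 1:3) {
    ideal <- numeric(length(t))
    for (j in seq_len(n + 1L))
      ideal <- strain_bump_add(ideal, t, k_ic[j], k_tc[j], k_apex[j], k_peak[j])
    ideal <- ideal - STRAIN_EPS
    # reproduce the analysis pipeline exactly: the emitted (once-filtered)
    # strain is filtered again and baseline-corrected by preprocess()
    dbl <- as.numeric(baseline_correct(
      lowpass(lowpass(ideal, fs, s_spec), fs, s_spec),
      floor_level = -STRAIN_EPS))
    m <- measure_strain_events(dbl, t, ic, tc, apex)
    ok <- stats::complete.cases(m)
    k_ic[ok] <- k_ic[ok] - (m[ok, "ic"] - ic[ok])
    k_tc[ok] <- k_tc[ok] - (m[ok, "tc"] - tc[ok])
    k_apex[ok] <- k_apex[ok] - (m[ok, "apex"] - apex[ok])
    k_peak[ok] <- pmax(k_peak[ok] - (m[ok, "peak"] - dr$strain_peak[ok]), 5)
  }
  ideal <- numeric(length(t))
  for (j in seq_len(n + 1L))
    ideal <- strain_bump_add(ideal, t, k_ic[j], k_tc[j], k_apex[j], k_peak[j])
  ideal <- ideal - STRAIN_EPS
  strain <- lowpass(ideal, fs, s_spec)

  # --- cane gyro, with swing-apex pre-compensation: the filtered apex of an
  # asymmetric peak drifts towards its flatter side, so the peak knot and
  # amplitude are adjusted until the pipeline-filtered apex lands on
  # PS = TC + ps_offset with value v_swing (the fall exponent is re-solved to
  # keep the sweep integral on target)
  g_spec <- filter_spec(6L, 8)
  v_adj <- dr$v_swing; ps_adj <- dr$ps_offset; p_adj <- dr$p
  lam_adj <- dr$lam
  build_gyro <- function() {
    g <- numeric(length(t))
    for (j in seq_len(n))
      g <- g + gyro_swing_eval(t, tc[j], ec[j], v_adj[j], ps_adj[j],
                               dr$lag[j], dr$d[j], p_adj[j], dr$r[j],
                               lam_adj[j])
    for (j in seq_len(n + 1L)) {  # stance lobes (incl. terminal plant)
      g1 <- if (j == 1L) 0.06 else max(dr$lag[j - 1L], 0) + GYRO_DIP_W + 0.03
      a <- ic[j] + g1; b <- tc[j] - 0.02
      if (b - a < 0.10) a <- b - 0.10
      i <- which(t >= a & t <= b)
      g[i] <- g[i] + dr$v_stance[j] * sin(pi * (t[i] - a) / (b - a))^2
    }
    g
  }
  for (iter in 1:2) {
    dblg <- lowpass(lowpass(build_gyro(), fs, g_spec), fs, g_spec)
    for (j in seq_len(n)) {
      i0 <- max(2L, floor((ps[j] - 0.08) * fs)); i1 <- min(length(t) - 1L, ceiling((ps[j] + 0.08) * fs))
      idx <- i0:i1
      k2 <- idx[which.max(dblg[idx])]
      aa <- dblg[k2 - 1L]; bb <- dblg[k2]; cc <- dblg[k2 + 1L]
      den <- aa - 2 * bb + cc
      t_hat <- t[k2] + if (den != 0) 0.5 * (aa - cc) / den / fs else 0
      v_hat <- bb - if (den != 0) 0.125 * (aa - cc)^2 / den else 0
      ps_new <- clamp(ps_adj[j] - (t_hat - ps[j]), 0.06,
                      dr$swing[j] + dr$lag[j] - GYRO_DIP_W - 0.04)
      v_new <- v_adj[j] * clamp(dr$v_swing[j] / max(v_hat, 1), 0.8, 1.25)
      ps_adj[j] <- ps_new; v_adj[j] <- v_new
      # re-solve the free shape parameter (plateau length, fall exponent or
      # rise exponent) so the sweep integral stays on target
      gi <- function(pp, rr, ll) swing_integral_grid(fs, tc[j], ec[j],
                                                     v_adj[j], ps_adj[j],
                                                     dr$lag[j], dr$d[j],
                                                     pp, rr, ll) - dr$theta_deg[j]
      lmax <- dr$swing[j] + dr$lag[j] - ps_adj[j] - GYRO_DIP_W - 0.06
      if (lam_adj[j] > 0 && gi(1, dr$r[j], 0.02) < 0 &&
          gi(1, dr$r[j], lmax) > 0) {
        lam_adj[j] <- stats::uniroot(function(ll) gi(1, dr$r[j], ll),
                                     c(0.02, lmax), tol = 1e-9)$root
      } else if (lam_adj[j] == 0 && gi(1, dr$r[j], 0) > 0 &&
                 gi(40, dr$r[j], 0) < 0) {
        p_adj[j] <- stats::uniroot(function(pp) gi(pp, dr$r[j], 0),
                                   c(1, 40), tol = 1e-9)$root
      } else if (lam_adj[j] == 0 && dr$r[j] > 0.5 && gi(40, 30, 0) < 0 &&
                 gi(40, 0.5, 0) > 0) {
        dr$r[j] <- stats::uniroot(function(rr) gi(40, rr, 0),
                                  c(0.5, 30), tol = 1e-9)$root
        p_adj[j] <- 40
      }
    }
  }
  gyro_x <- lowpass(build_gyro(), fs, g_spec)

  # --- shank stream (own clock = cane clock - stream_shift)
  dt_sh <- 1 / cfg$fs_shank
  n_sh <- floor((t_end - stream_shift) / dt_sh) + 1L
  t_sh <- (seq_len(n_sh) - 1L) * dt_sh
  walk <- t_sh + stream_shift
  tcs <- ic[seq_len(n)] + dr$shank_fr[seq_len(n)] * (ec - ic[seq_len(n)])
  pss <- (tcs + SHANK_DIP_W + ec - SHANK_DIP_W) / 2  # symmetric swing bump apex
  sh <- shank_eval(walk, boundaries = ic, tcs = tcs, pss = pss,
                   v = dr$shank_v[seq_len(n)])
  sh <- lowpass(sh, cfg$fs_shank, g_spec)

  nz <- function(m, sd) if (sd > 0) stats::rnorm(m, 0, sd) else numeric(m)
  cane <- cane_recording(
    time = t,
    strain = strain + nz(length(t), cfg$noise_sd_strain),
    gyro_x = gyro_x + nz(length(t), cfg$noise_sd_gyro),
    gyro_y = nz(length(t), cfg$noise_sd_gyro),
    gyro_z = nz(length(t), cfg$noise_sd_gyro),
    accel_x = numeric(length(t)), accel_y = numeric(length(t)),
    accel_z = numeric(length(t)),
    sample_rate = fs,
    meta = c(meta, list(condition = profile$name,
                        cane_length_m = profile$cane_length_m,
                        synthetic = TRUE))
  )
  shank <- shank_recording(
    time = t_sh, gyro_ap = sh + nz(n_sh, cfg$noise_sd_gyro),
    sample_rate = cfg$fs_shank,
    meta = c(meta, list(condition = profile$name, synthetic = TRUE))
  )

  sidx <- seq_len(n)
  events <- rbind(
    data.frame(stride = rep(sidx, each = 4L),
               event = rep(c("IC", "TC", "PS", "EC"), n),
               t_s = as.vector(rbind(ic[sidx], tc[sidx], ps, ec)),
               stream = "cane"),
    data.frame(stride = rep(sidx, each = 4L),
               event = rep(c("IC", "TC", "PS", "EC"), n),
               t_s = as.vector(rbind(ic[sidx] - stream_shift,
                                     tcs - stream_shift,
                                     pss - stream_shift,
                                     ec - stream_shift)),
               stream = "shank")
  )
  truth <- list(events = events, params = dr[sidx, , drop = FALSE],
                start_offset = stream_shift, seed = seed)
  list(cane = cane, shank = shank, truth = truth)
}

#' Generate a full synthetic study
#'
#' Produces `n_participants x length(conditions)` trials.  Participant-level
#' mean shifts are drawn once per participant ([participant_shifts()]) and
#' shared across that participant's conditions, so condition contrasts are
#' paired within participants.  Trial seeds are derived from `cfg$seed`, so
#' the whole study is reproducible.
#'
#' @param cfg a [study_config()].
#' @param keep_streams keep the waveforms (`TRUE`, default) or only truth
#'   records (`FALSE`; useful for large designs).
#' @return List with `plan` (data.frame: participant, condition, seed,
#'   stream shift) and `trials` (list of [generate_trial()] results, in plan
#'   order).
#' @export
generate_study <- function(cfg, keep_streams = TRUE) {
  plan <- study_plan(cfg)
  profs <- default_profiles()
  shifts <- plan$shifts
  trials <- vector("list", nrow(plan$grid))
  for (i in seq_len(nrow(plan$grid))) {
    row <- plan$grid[i, ]
    tr <- generate_trial(profs[[row$condition]], cfg,
                         shift = shifts[row$participant, ],
                         seed = row$seed, stream_shift = row$stream_shift,
                         meta = list(participant = row$participant))
    if (!keep_streams) tr$cane <- tr$shank <- NULL
    trials[[i]] <- tr
  }
  list(plan = plan$grid, trials = trials)
}

# deterministic per-trial seeds and participant shifts for a study design
study_plan <- function(cfg) {
  set.seed(cfg$seed)
  shifts <- participant_shifts(cfg)
  grid <- expand.grid(participant = seq_len(cfg$n_participants),
                      condition = cfg$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  grid$stream_shift <- stats::runif(nrow(grid), -1, 1)
  list(grid = grid, shifts = shifts)
}
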