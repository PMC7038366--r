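FEATURE_NAMES <- c("max_pv_swing", "max_pv_stance", "max_pv_time_wrt_tc",
                   "swing_stance_ratio", "max_strain",
                   "max_strain_time_wrt_ic", "stride_length", "diff_ic")

#' Pendulum-model stride length
#'
#' The cane is modelled as a pendulum of length `cane_length` pivoting about
#' its tip contact: the swing-phase sweep angle is the trapezoidal time
#' integral of the AP angular velocity over (TC, EC], and the stride length
#' is the chord `2 L sin(theta / 2)`.  Negative sweep angles clamp to zero
#' length.
#'
#' @param cane_gyro_ap cane AP velocity (deg/s), filtered.
#' @param stride stride record with `tc` and `ec` times (seconds), e.g. one
#'   row of [assemble_strides()].
#' @param sample_rate Hz.
#' @param cane_length cane length in metres.
#' @return Stride length in metres.
#' @export
stride_length_pendulum <- function(cane_gyro_ap, stride, sample_rate,
                                   cane_length) {
  if (cane_length <= 0) stop("cane_length must be > 0", call. = FALSE)
  t <- (seq_along(cane_gyro_ap) - 1L) / sample_rate
  idx <- which(t > stride$tc & t <= stride$ec)
  theta_deg <- trapz(t[idx], cane_gyro_ap[idx])
  theta <- max(theta_deg, 0) * pi / 180
  2 * cane_length * sin(clamp(theta / 2, 0, pi / 2))
}

#' Per-stride gait features from cane data
#'
#' Computes the cane-derived members of the eight-feature set for one valid
#' stride: peak AP velocity in swing (TC, EC] and stance [IC, TC] (deg/s),
#' the swing peak's time after TC (ms), the swing-stance duration ratio, the
#' peak strain on [IC, TC] (ADC counts) and its time after IC (ms), and the
#' pendulum stride length (m).  The Difference-in-IC member is computed
#' separately by [diff_ic()] because it needs both segmentation algorithms.
#'
#' @param stride one row of [assemble_strides()] (must be valid).
#' @param cane preprocessed [cane_recording()].
#' @param cane_length cane length in metres (defaults to
#'   `cane$meta$cane_length_m`).
#' @return Named list of feature values.
#' @export
stride_features <- function(stride, cane, cane_length = NULL) {
  if (!isTRUE(stride$valid))
    stop(sprintf("stride %s is not valid (%s)", stride$stride, stride$reason),
         call. = FALSE)
  if (is.null(cane_length)) cane_length <- cane$meta$cane_length_m
  if (is.null(cane_length)) stop("cane_length not supplied and absent from meta",
                                 call. = FALSE)
  t <- cane$time
  if (stride$ic < t[1L] || stride$ec > t[length(t)])
    stop("stride events outside the recording span", call. = FALSE)
  stance <- which(t >= stride$ic & t <= stride$tc)
  swing <- which(t > stride$tc & t <= stride$ec)
  g <- cane$gyro_x; s <- cane$strain
  i_sw <- swing[which.max(g[swing])]
  i_st <- stance[which.max(s[stance])]
  list(
    max_pv_swing = g[i_sw],
    max_pv_stance = max(g[stance]),
    max_pv_time_wrt_tc = (refine_apex(g, t, i_sw) - stride$tc) * 1000,
    swing_stance_ratio = (stride$ec - stride$tc) / (stride$tc - stride$ic),
    max_strain = s[i_st],
    max_strain_time_wrt_ic = (t[i_st] - stride$ic) * 1000,
    stride_length = stride_length_pendulum(g, stride, cane$sample_rate,
                                           cane_length)
  )
}

#' Shank-derived feature subset
#'
#' The gyroscope-only analogues computed from a shank stride segmented by
#' GPD: peak AP velocities, swing-peak timing, swing-stance ratio, and a
#' pendulum-style stride length using a configurable effective limb length
#' (a validation convenience, not a biomechanical claim).  Strain-based
#' features are `NA`.
#'
#' @param stride one valid row of [assemble_strides()] on the shank stream.
#' @param shank preprocessed [shank_recording()].
#' @param limb_length effective limb length in metres (default 0.9).
#' @return Named list; strain members are `NA`.
#' @export
shank_features <- function(stride, shank, limb_length = 0.9) {
  if (!isTRUE(stride$valid))
    stop(sprintf("stride %s is not valid (%s)", stride$stride, stride$reason),
         call. = FALSE)
  t <- shank$time
  stance <- which(t >= stride$ic & t <= stride$tc)
  swing <- which(t > stride$tc & t <= stride$ec)
  g <- shank$gyro_ap
  i_sw <- swing[which.max(g[swing])]
  list(
    max_pv_swing = g[i_sw],
    max_pv_stance = max(g[stance]),
    max_pv_time_wrt_tc = (t[i_sw] - stride$tc) * 1000,
    swing_stance_ratio = (stride$ec - stride$tc) / (stride$tc - stride$ic),
    max_strain = NA_real_,
    max_strain_time_wrt_ic = NA_real_,
    stride_length = stride_length_pendulum(g, stride, shank$sample_rate,
                                           limb_length)
  )
}

#' MSMF-GPD Difference in IC
#'
#' Pairs initial-contact events detected by the two algorithms on the same
#' cane recording (greedy nearest pairing within `tol` seconds) and returns
#' the per-pair difference IC_MSMF - IC_GPD in milliseconds.  A positive GPD
#' lag (the gyroscope minimum trailing the strain zero-crossing) yields a
#' negative difference.
#'
#' @param msmf_events MSMF gait-event data.frame.
#' @param gpd_events_on_cane GPD gait-event data.frame from the cane
#'   gyroscope.
#' @param tol pairing tolerance in seconds (default: half the default
#'   stride-duration bound, 1.5 s).
#' @return List: `diff_ms` (per-pair differences), `pairs` (data.frame
#'   `ic_msmf`, `ic_gpd`, `diff_ms`), `unpaired_msmf`, `unpaired_gpd`.
#' @export
diff_ic <- function(msmf_events, gpd_events_on_cane, tol = 1.5) {
  icm <- sort(unique(msmf_events$t_s[msmf_events$event == "IC"]))
  icg <- attr(gpd_events_on_cane, "ic_candidates")
  if (is.null(icg))
    icg <- sort(unique(gpd_events_on_cane$t_s[
      gpd_events_on_cane$event %in% c("IC", "EC")]))
  if (!length(icm) || !length(icg))
    return(list(diff_ms = numeric(0),
                pairs = data.frame(ic_msmf = numeric(0), ic_gpd = numeric(0),
                                   diff_ms = numeric(0)),
                unpaired_msmf = icm, unpaired_gpd = icg))
  cand <- expand.grid(i = seq_along(icm), j = seq_along(icg))
  cand$dt <- abs(icm[cand$i] - icg[cand$j])
  cand <- cand[cand$dt <= tol, , drop = FALSE]
  cand <- cand[order(cand$dt), , drop = FALSE]
  used_m <- logical(length(icm)); used_g <- logical(length(icg))
  pi_ <- integer(0); pj <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_m[i] && !used_g[j]) {
      used_m[i] <- TRUE; used_g[j] <- TRUE
      pi_ <- c(pi_, i); pj <- c(pj, j)
    }
  }
  ord <- order(icm[pi_])
  pi_ <- pi_[ord]; pj <- pj[ord]
  d <- (icm[pi_] - icg[pj]) * 1000
  list(diff_ms = d,
       pairs = data.frame(ic_msmf = icm[pi_], ic_gpd = icg[pj], diff_ms = d),
       unpaired_msmf = icm[!used_m], unpaired_gpd = icg[!used_g])
}

#' Tidy per-stride feature table
#'
#' One record per stride and feature: `participant`, `condition`,
#' `stride_index`, `feature`, `value`, `source`.
#'
#' @param strides valid strides ([assemble_strides()] rows).
#' @param cane preprocessed [cane_recording()].
#' @param cane_length metres.
#' @param participant,condition labels.
#' @param diffs optional [diff_ic()] result merged in as the `diff_ic`
#'   feature (paired by nearest stride IC).
#' @return data.frame in tidy layout.
#' @export
feature_table <- function(strides, cane, cane_length = NULL,
                          participant = NA, condition = NA, diffs = NULL) {
  strides <- strides[strides$valid, , drop = FALSE]
  rows <- lapply(seq_len(nrow(strides)), function(i) {
    f <- stride_features(strides[i, ], cane, cane_length)
    data.frame(participant = participant, condition = condition,
               stride_index = strides$stride[i],
               feature = names(f), value = unlist(f, use.names = FALSE),
               source = "cane", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(diffs) && nrow(diffs$pairs)) {
    idx <- vapply(diffs$pairs$ic_msmf, function(x)
      strides$stride[which.min(abs(strides$ic - x))], 0L)
    keep <- abs(strides$ic[match(idx, strides$stride)] - diffs$pairs$ic_msmf) < 1e-6
    out <- rbind(out, data.frame(
      participant = participant, condition = condition,
      stride_index = idx[keep], feature = "diff_ic",
      value = diffs$pairs$diff_ms[keep], source = "cane",
      stringsAsFactors = FALSE))
  }
  out
}

#' Per-condition feature summary
#'
#' Mean and SD of every feature per condition (and source stream), pooled
#' over strides, plus the per-participant means that feed the
#' repeated-measures stage.
#'
#' @param table tidy feature table ([feature_table()] rows, possibly many
#'   trials).
#' @return data.frame `condition`, `feature`, `source`, `mean`, `sd`, `n`;
#'   per-participant means in `attr(, "participant_means")`.
#' @export
condition_summary <- function(table) {
  if (!nrow(table)) stop("empty feature table", call. = FALSE)
  agg <- function(df, by) {
    sp <- split(df, df[by], drop = TRUE)
    out <- lapply(sp, function(g) {
      r <- g[1L, by, drop = FALSE]
      r$mean <- mean(g$value); r$sd <- stats::sd(g$value); r$n <- nrow(g)
      r
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  smry <- agg(table, c("condition", "feature", "source"))
  smry$sd[smry$n == 1L] <- 0
  pm <- agg(table, c("participant", "condition", "feature", "source"))
  attr(smry, "participant_means") <- pm[, c("participant", "condition",
                                            "feature", "source", "mean")]
  smry
}

#' Subject-by-condition matrix for one feature
#'
#' Reshapes the participant means attached to a [condition_summary()] into
#' the complete n x k matrix required by [rm_anova_oneway()].
#'
#' @param summary a [condition_summary()] result.
#' @param feature feature name.
#' @param source source stream (default "cane").
#' @return Numeric matrix, participants x conditions.
#' @export
subject_condition_matrix <- function(summary, feature, source = "cane") {
  pm <- attr(summary, "participant_means")
  pm <- pm[pm$feature == feature & pm$source == source, , drop = FALSE]
  if (!nrow(pm)) stop(sprintf("no participant means for feature '%s'", feature),
                      call. = FALSE)
  conds <- unique(pm$condition)
  parts <- sort(unique(pm$participant))
  m <- matrix(NA_real_, length(parts), length(conds),
              dimnames = list(parts, conds))
  m[cbind(match(pm$participant, parts), match(pm$condition, conds))] <- pm$mean
  m
}
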