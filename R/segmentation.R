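#' Segmentation configuration
#'
#' Tunables shared by the two stride-segmentation algorithms.
#'
#' @param similarity_threshold minimum normalized template correlation for a
#'   matched-filter peak to seed a stride (default 0.5, i.e. the 50%
#'   similarity rule).
#' @param ic_window_s half-width of the window around a matched-filter peak
#'   in which the IC zero-crossing is searched (default 0.5 s).
#' @param template_strides number of loading bumps averaged into the trial
#'   template (default 5).
#' @param gpd_threshold peak-swing detection threshold in deg/s, or `"auto"`
#'   to derive it from the signal with [auto_threshold()].
#' @param min_stride_s,max_stride_s stride-duration plausibility bounds in
#'   seconds (defaults 0.4 and 3.0).
#' @param min_prominence minimum prominence (deg/s) for a gyroscope local
#'   minimum to count as a gait event candidate; suppresses noise chatter on
#'   flat segments.
#' @param extremum_window_s half-width (s) of the neighbourhood a local
#'   extremum must dominate.
#' @return A `seg_config` object.
#' @export
seg_config <- function(similarity_threshold = 0.5, ic_window_s = 0.5,
                       template_strides = 5L, gpd_threshold = "auto",
                       min_stride_s = 0.4, max_stride_s = 3.0,
                       min_prominence = 5, extremum_window_s = 0.15) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
            ic_window_s > 0, min_stride_s > 0, max_stride_s > min_stride_s)
  structure(list(similarity_threshold = similarity_threshold,
                 ic_window_s = ic_window_s,
                 template_strides = as.integer(template_strides),
                 gpd_threshold = gpd_threshold,
                 min_stride_s = min_stride_s, max_stride_s = max_stride_s,
                 min_prominence = min_prominence,
                 extremum_window_s = extremum_window_s),
            class = "seg_config")
}

gait_events <- function(stride, event, t_s, source) {
  data.frame(stride = as.integer(stride), event = event, t_s = t_s,
             source = source, stringsAsFactors = FALSE)
}

# ---- primitive detectors ----------------------------------------------------

# Positive (dir = +1) or negative (dir = -1) zero-crossings with hysteresis:
# a positive crossing fires when the signal has been below -h since the last
# firing and rises through zero; the crossing time is linearly interpolated.
# With `confirm = TRUE` a candidate only fires if the signal then stays above
# -h for `confirm_s` seconds: a genuine loading onset keeps the gauge loaded
# for the whole stance phase, while a filter-ringing wiggle falls straight
# back to the unloaded floor.  Rejected candidates do not consume the
# hysteresis arming.
zero_crossings <- function(x, t, h, dir = 1L, confirm = FALSE,
                           confirm_s = 0.22) {
  if (dir < 0) x <- -x
  out <- numeric(0)
  cross <- which(x[-length(x)] < 0 & x[-1L] >= 0)
  arm_pts <- which(x < -h)
  if (!length(cross) || !length(arm_pts)) return(numeric(0))
  confirm_n <- max(1L, round(confirm_s / (t[2L] - t[1L])))
  last_arm <- -Inf
  ai <- 1L
  for (ci in cross) {
    # any armed sample since previous accepted crossing and before ci?
    while (ai <= length(arm_pts) && arm_pts[ai] <= ci) {
      last_arm <- arm_pts[ai]; ai <- ai + 1L
    }
    if (!is.finite(last_arm)) next
    if (confirm) {
      nxt <- arm_pts[arm_pts > ci]
      if (length(nxt) && nxt[1L] - ci <= confirm_n) next  # ringing, stay armed
    }
    out <- c(out, t[ci] + (0 - x[ci]) / (x[ci + 1L] - x[ci]) * (t[ci + 1L] - t[ci]))
    last_arm <- -Inf
  }
  out
}

# robust hysteresis half-height for a strain signal: 3 x MAD of the
# unloaded-phase samples (located via their density mode, so loading bumps
# and ringing excursions cannot inflate the scale), floored at 1 count
strain_hysteresis <- function(x) {
  max(3 * floor_stats(x)$noise, 1)
}

# local minima that dominate a +/- window and have at least `prominence`
# depth relative to the lower of the two flanking window maxima
local_minima <- function(x, win, prominence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    lo <- max(1L, i - win); hi <- min(n, i + win)
    if (x[i] > min(x[lo:hi])) next
    prom <- min(max(x[lo:i]), max(x[i:hi])) - x[i]
    keep[j] <- prom >= prominence
  }
  cand[keep]
}

#' Automatic peak-swing threshold
#'
#' Derives a peak-swing detection threshold from the positive excursions of
#' an AP angular-velocity signal: half of the 95th percentile of the positive
#' samples.  On a shank stream, whose stance activity is a small fraction of
#' the swing peak, this lands between the stance and swing lobes.  On a cane
#' stream the stance-lobe peak typically exceeds half the swing peak, so the
#' threshold admits stance-lobe peaks as well; the event logic tolerates
#' this because both kinds of peak share the same bracketing minima.  Supply
#' a manual `gpd_threshold` to override.
#'
#' @param gyro_ap AP angular velocity, deg/s.
#' @return Threshold in deg/s.
#' @export
auto_threshold <- function(gyro_ap) {
  pos <- gyro_ap[gyro_ap > 0]
  if (!length(pos)) stop("no positive samples: cannot derive a threshold", call. = FALSE)
  0.5 * stats::quantile(pos, 0.95, names = FALSE)
}

#' Gyroscope peak-swing detection
#'
#' Finds one peak-swing (PS) event per contiguous supra-threshold excursion
#' of the AP velocity, at the excursion's maximum (earliest sample on ties).
#' Peaks closer than `min_stride_s` are merged, keeping the larger.
#'
#' @param gyro_ap AP angular velocity, deg/s.
#' @param sample_rate Hz.
#' @param threshold detection threshold, deg/s (> 0).
#' @param min_stride_s minimum separation between PS events, seconds.
#' @return Integer vector of PS sample indices (possibly empty).
#' @export
detect_ps_gpd <- function(gyro_ap, sample_rate, threshold,
                          min_stride_s = 0.4) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  above <- gyro_ap > threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  peaks <- apply(runs, 1L, function(se) {
    se[1L] - 1L + which.max(gyro_ap[se[1L]:se[2L]])
  })
  peaks <- sort(peaks)
  min_gap <- min_stride_s * sample_rate
  keep <- rep(TRUE, length(peaks))
  i <- 1L
  while (i < length(peaks)) {
    j <- i + 1L
    while (j <= length(peaks) && keep[j] == FALSE) j <- j + 1L
    if (j > length(peaks)) break
    if (peaks[j] - peaks[i] < min_gap) {
      if (gyro_ap[peaks[j]] > gyro_ap[peaks[i]]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
    } else i <- j
  }
  peaks[keep]
}

#' Gait events from peak-swing detections (GPD)
#'
#' For each PS event the terminal contact (TC) is the nearest qualified
#' local minimum before it and the following minimum marks the initial
#' contact of the next cycle; during continuous walking the end of contact
#' (EC) of a stride is the IC of the next.  A stride therefore spans
#' (IC_k, TC_{k+1}, PS_{k+1}, EC_k = IC_{k+1}) in detection order; the
#' opening IC of the first stride is taken as the nearest qualified minimum
#' preceding the first TC.  Cycles lacking a bracketing minimum within
#' `max_stride_s` are dropped.
#'
#' @param gyro_ap AP angular velocity (deg/s), already low-pass filtered.
#' @param sample_rate Hz.
#' @param ps_idx PS sample indices from [detect_ps_gpd()].
#' @param cfg a [seg_config()].
#' @param source label stored in the `source` column.
#' @return A gait-event data.frame (`stride`, `event`, `t_s`, `source`);
#'   the EC of stride k equals the IC of stride k+1.  The final stride's EC
#'   is flagged via `attr(, "provisional_last")` when it had to be taken
#'   from a trailing minimum.
#' @export
events_from_ps_gpd <- function(gyro_ap, sample_rate, ps_idx,
                               cfg = seg_config(), source = "GPD") {
  t <- (seq_along(gyro_ap) - 1L) / sample_rate
  if (!length(ps_idx)) return(gait_events(integer(0), character(0), numeric(0), character(0)))
  win <- max(1L, round(cfg$extremum_window_s * sample_rate))
  mins <- local_minima(gyro_ap, win, cfg$min_prominence)
  max_gap <- cfg$max_stride_s * sample_rate
  np <- length(ps_idx)
  # Between two swing peaks the gait minima appear in order: the boundary
  # (IC/EC) valley first, then the next cycle's TC valley.  Qualified minima
  # in an interval must also pass a depth gate (40% of the interval's deepest
  # value), which rejects shallow filter ripples on the lobe shoulders.
  deep_in <- function(lo, hi) {
    cand <- mins[mins > lo & mins < hi]
    if (!length(cand)) return(integer(0))
    v <- gyro_ap[cand]
    cand[v <= 0.25 * min(v)]
  }
  cyc <- lapply(seq_len(np), function(k) {
    p <- ps_idx[k]
    lo <- max(if (k > 1L) ps_idx[k - 1L] else -Inf, p - max_gap)
    hi <- min(if (k < np) ps_idx[k + 1L] else Inf, p + max_gap)
    before <- deep_in(lo, p); after <- deep_in(p, hi)
    list(ps = p,
         tc = if (length(before)) before[length(before)] else NA_integer_,
         m = if (length(after)) after[which.min(gyro_ap[after])] else NA_integer_)
  })
  ok <- vapply(cyc, function(cc) !is.na(cc$tc) && !is.na(cc$m), TRUE)
  cyc <- cyc[ok]
  if (!length(cyc)) return(gait_events(integer(0), character(0), numeric(0), character(0)))
  tcs <- vapply(cyc, `[[`, 0L, "tc")
  pss <- vapply(cyc, `[[`, 0L, "ps")
  ms <- vapply(cyc, `[[`, 0L, "m")
  # opening IC: last deep minimum preceding the first TC
  first_ic <- {
    cand <- deep_in(tcs[1L] - max_gap, tcs[1L])
    if (length(cand)) cand[length(cand)] else NA_integer_
  }
  ics <- c(first_ic, ms)
  ev <- list()
  stride <- 0L
  for (k in seq_along(cyc)) {
    ic_k <- ics[k]; ec_k <- ms[k]
    if (is.na(ic_k) || ic_k >= tcs[k]) next
    stride <- stride + 1L
    ev[[length(ev) + 1L]] <- gait_events(
      rep(stride, 4L), c("IC", "TC", "PS", "EC"),
      t[c(ic_k, tcs[k], pss[k], ec_k)], source)
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) out <- gait_events(integer(0), character(0), numeric(0), character(0))
  # initial-contact candidate landmarks (the post-swing minima), useful to
  # consumers like diff_ic() even when full strides cannot be assembled
  attr(out, "ic_candidates") <- sort(unique(t[stats::na.omit(c(first_ic, ms))]))
  out
}

#' Build a strain template from a trial
#'
#' Extracts the first `n` well-separated loading bumps (contiguous runs
#' above half a robust upper level, padded to the surrounding positive
#' region; the level is lowered stepwise when loading peaks are very
#' uneven), resamples them to their median length, averages, removes the
#' mean and scales to unit energy.  [canonical_template()] provides a
#' shape-only fallback for trials too short to supply `n` bumps.
#'
#' @param strain baseline-corrected strain signal.
#' @param sample_rate Hz.
#' @param n number of bumps to average (default 5).
#' @return Numeric template (zero-mean, unit energy).
#' @export
build_template <- function(strain, sample_rate, n = 5L) {
  # scan at half of a robust upper level (not the absolute maximum, so one
  # heavy loading bump cannot hide the typical ones); if the loading peaks
  # are very uneven, lower the level until enough bumps emerge
  q98 <- stats::quantile(strain, 0.98, names = FALSE)
  if (q98 <= 0) stop("strain has no positive loading phase", call. = FALSE)
  min_run <- max(2L, round(0.08 * sample_rate))
  runs <- NULL
  for (frac in c(0.5, 0.35, 0.25, 0.15)) {
    above <- strain > frac * q98
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    runs <- cbind(starts[keep], ends[keep])
    if (nrow(runs) >= n) break
  }
  if (nrow(runs) < n)
    stop(sprintf("found only %d loading bumps; %d required for the template",
                 nrow(runs), n), call. = FALSE)
  runs <- runs[seq_len(n), , drop = FALSE]
  segs <- lapply(seq_len(n), function(i) {
    a <- runs[i, 1L]; b <- runs[i, 2L]
    while (a > 1L && strain[a - 1L] > 0) a <- a - 1L
    while (b < length(strain) && strain[b + 1L] > 0) b <- b + 1L
    strain[a:b]
  })
  len <- stats::median(vapply(segs, length, 0L))
  resampled <- vapply(segs, function(s) {
    stats::approx(seq_along(s), s, xout = seq(1, length(s), length.out = len))$y
  }, numeric(len))
  tpl <- rowMeans(resampled)
  tpl <- tpl - mean(tpl)
  en <- sqrt(sum(tpl^2))
  if (en == 0) stop("degenerate template (zero energy)", call. = FALSE)
  tpl / en
}

#' Canonical loading-bump template
#'
#' A raised-cosine-squared loading bump of the given duration, mean-removed
#' and unit-energy scaled: the fallback template for trials too short for
#' [build_template()].
#'
#' @param sample_rate Hz.
#' @param stance_s nominal loading-phase duration in seconds (default
#'   0.65, the control-condition stance).
#' @return Numeric template.
#' @export
canonical_template <- function(sample_rate, stance_s = 0.65) {
  nL <- max(8L, round(stance_s * sample_rate))
  tpl <- sin(pi * seq_len(nL) / (nL + 1L))^2
  tpl <- tpl - mean(tpl)
  tpl / sqrt(sum(tpl^2))
}

#' Normalized matched-filter similarity trace
#'
#' Slides the template over the strain signal and returns the normalized
#' (Pearson) cross-correlation at every alignment, assigned to the first
#' sample of the window - the template starts at the loading onset, so a
#' similarity peak sits at the stride's initial contact regardless of the
#' loading-phase duration.  Values lie in [-1, 1]; alignments whose window
#' extends beyond the signal are set to 0.
#'
#' @param strain strain signal.
#' @param template template from [build_template()] (any template is
#'   internally mean-removed and energy-normalized).
#' @return Numeric trace, same length as `strain`.
#' @export
msmf_trace <- function(strain, template) {
  L <- length(template)
  n <- length(strain)
  if (L < 2L) stop("template must contain at least two samples", call. = FALSE)
  if (L >= n) stop("template must be shorter than the signal", call. = FALSE)
  tpl <- template - mean(template)
  ten <- sqrt(sum(tpl^2))
  if (ten == 0) stop("zero-energy template", call. = FALSE)
  tpl <- tpl / ten
  # windowed sums via cumulative sums
  cx <- c(0, cumsum(strain))
  cx2 <- c(0, cumsum(strain^2))
  sx <- cx[(L + 1L):(n + 1L)] - cx[1L:(n - L + 1L)]
  sx2 <- cx2[(L + 1L):(n + 1L)] - cx2[1L:(n - L + 1L)]
  # correlation numerator via FFT-free convolution (stats::filter)
  num <- stats::filter(strain, rev(tpl), method = "convolution", sides = 1)
  num <- as.numeric(num)[L:n]                 # aligned to window start 1..n-L+1
  den <- sqrt(pmax(sx2 - sx^2 / L, 0))
  r <- ifelse(den > 1e-12, num / den, 0)      # tpl is zero-mean: no mean term
  out <- numeric(n)
  out[seq_len(n - L + 1L)] <- pmin(pmax(r, -1), 1)
  out
}

#' Multi-sensor matched-filter event detection (MSMF)
#'
#' Implements the matched-filter stride rules on cane data: every similarity
#' peak above `similarity_threshold` proposes a stride; the IC is the
#' nearest positive strain zero-crossing within `ic_window_s` of the peak;
#' TC is the first negative strain crossing after IC; PS is the maximum of
#' the cane AP velocity after TC (bounded by the next IC); EC is the first
#' positive strain crossing after PS (the next stride's IC during continuous
#' walking).  Cycles failing any step or the stride-duration bounds are
#' dropped, with the reason recorded in `attr(, "dropped")`.
#'
#' @param strain baseline-corrected, filtered strain.
#' @param cane_gyro_ap filtered cane AP velocity (deg/s).
#' @param sample_rate Hz.
#' @param template strain template ([build_template()]).
#' @param cfg a [seg_config()].
#' @return Gait-event data.frame (`stride`, `event`, `t_s`, `source`).
#' @export
detect_events_msmf <- function(strain, cane_gyro_ap, sample_rate, template,
                               cfg = seg_config()) {
  stopifnot(length(strain) == length(cane_gyro_ap))
  t <- (seq_along(strain) - 1L) / sample_rate
  trace <- msmf_trace(strain, template)
  pk <- detect_trace_peaks(trace, cfg$similarity_threshold,
                           round(cfg$min_stride_s * sample_rate))
  empty <- gait_events(integer(0), character(0), numeric(0), character(0))
  if (!length(pk)) return(empty)
  h <- strain_hysteresis(strain)
  pos <- zero_crossings(strain, t, h, dir = 1L, confirm = TRUE)
  neg <- zero_crossings(strain, t, h, dir = -1L)
  if (!length(pos)) return(empty)
  # IC candidates: nearest positive crossing within the window of each peak
  ics <- vapply(pk, function(i) {
    d <- abs(pos - t[i])
    j <- which.min(d)
    if (d[j] <= cfg$ic_window_s) pos[j] else NA_real_
  }, 0)
  ics <- sort(unique(ics[!is.na(ics)]))
  dropped <- character(0)
  ev <- list(); stride <- 0L
  for (k in seq_along(ics)) {
    ic_t <- ics[k]
    next_ic <- if (k < length(ics)) ics[k + 1L] else Inf
    tc_t <- neg[neg > ic_t][1L]
    if (is.na(tc_t) || tc_t >= next_ic) {
      dropped <- c(dropped, sprintf("stride at %.3f s: no TC crossing", ic_t)); next
    }
    ps_hi <- min(ic_t + cfg$max_stride_s, next_ic)
    idx <- which(t > tc_t & t <= ps_hi)
    if (!length(idx)) {
      dropped <- c(dropped, sprintf("stride at %.3f s: empty PS window", ic_t)); next
    }
    ps_t <- refine_apex(cane_gyro_ap, t, idx[which.max(cane_gyro_ap[idx])])
    ec_t <- pos[pos > ps_t][1L]
    if (is.na(ec_t)) {
      dropped <- c(dropped, sprintf("stride at %.3f s: no EC crossing", ic_t)); next
    }
    dur <- ec_t - ic_t
    if (dur < cfg$min_stride_s || dur > cfg$max_stride_s) {
      dropped <- c(dropped, sprintf("stride at %.3f s: duration %.2f s out of bounds", ic_t, dur)); next
    }
    if (!(ic_t < tc_t && tc_t < ps_t && ps_t < ec_t)) {
      dropped <- c(dropped, sprintf("stride at %.3f s: event order violated", ic_t)); next
    }
    stride <- stride + 1L
    ev[[length(ev) + 1L]] <- gait_events(rep(stride, 4L),
                                         c("IC", "TC", "PS", "EC"),
                                         c(ic_t, tc_t, ps_t, ec_t), "MSMF")
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) out <- empty
  attr(out, "dropped") <- dropped
  out
}

# sub-sample apex time by quadratic interpolation through the argmax sample
# and its neighbours (falls back to the sample time at signal edges)
refine_apex <- function(x, t, i) {
  if (i <= 1L || i >= length(x)) return(t[i])
  den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (den == 0) return(t[i])
  delta <- 0.5 * (x[i - 1L] - x[i + 1L]) / den
  t[i] + max(min(delta, 0.5), -0.5) * (t[2L] - t[1L])
}

# local maxima of the similarity trace above a threshold, separated by at
# least min_gap samples (keep the larger on conflicts; earliest on ties)
detect_trace_peaks <- function(trace, threshold, min_gap) {
  cand <- which(diff(sign(diff(trace))) < 0) + 1L
  cand <- cand[trace[cand] > threshold]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-trace[cand], cand)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Assemble gait events into strides
#'
#' Groups a time-sorted gait-event table into (IC, TC, PS, EC) quadruples.
#' Groups violating the event order and incomplete trailing groups are
#' returned as invalid, with the reason in `reason`.
#'
#' @param events gait-event data.frame (`stride`, `event`, `t_s`, `source`).
#' @return data.frame with one row per stride: `stride`, `ic`, `tc`, `ps`,
#'   `ec` (seconds), `source`, `valid`, `reason`.
#' @export
assemble_strides <- function(events) {
  if (!nrow(events))
    return(data.frame(stride = integer(0), ic = numeric(0), tc = numeric(0),
                      ps = numeric(0), ec = numeric(0), source = character(0),
                      valid = logical(0), reason = character(0)))
  out <- lapply(split(events, events$stride), function(g) {
    get1 <- function(kind) {
      v <- g$t_s[g$event == kind]
      if (length(v)) v[1L] else NA_real_
    }
    ic <- get1("IC"); tc <- get1("TC"); ps <- get1("PS"); ec <- get1("EC")
    valid <- TRUE; reason <- ""
    if (anyNA(c(ic, tc, ps, ec))) { valid <- FALSE; reason <- "incomplete" }
    else if (!(ic < tc && tc < ps && ps < ec)) { valid <- FALSE; reason <- "order" }
    data.frame(stride = g$stride[1L], ic = ic, tc = tc, ps = ps, ec = ec,
               source = g$source[1L], valid = valid, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$stride), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cane-shank synchronization offset
#'
#' The two systems start independently; participants stand still holding the
#' cane off the ground before walking, so the cane's first positive strain
#' zero-crossing and the shank's first prominent local minimum in AP
#' velocity mark the same gait instant.  The offset (cane clock minus shank
#' clock) aligns the streams.
#'
#' @param cane preprocessed [cane_recording()].
#' @param shank preprocessed [shank_recording()].
#' @param cfg a [seg_config()] (prominence settings).
#' @return Offset in seconds.
#' @export
sync_offset <- function(cane, shank, cfg = seg_config()) {
  h <- strain_hysteresis(cane$strain)
  pos <- zero_crossings(cane$strain, cane$time, h, dir = 1L, confirm = TRUE)
  if (!length(pos)) stop("synchronization failed: no strain zero-crossing", call. = FALSE)
  win <- max(1L, round(cfg$extremum_window_s * shank$sample_rate))
  mins <- local_minima(shank$gyro_ap, win, cfg$min_prominence)
  if (!length(mins)) stop("synchronization failed: no shank local minimum", call. = FALSE)
  pos[1L] - shank$time[mins[1L]]
}

#' Segment a trial with either or both algorithms
#'
#' Convenience wrapper: preprocesses nothing (pass preprocessed recordings),
#' builds the per-trial template, and runs MSMF on the cane and/or GPD on
#' the requested stream.
#'
#' @param cane preprocessed [cane_recording()].
#' @param shank optional preprocessed [shank_recording()].
#' @param method `"msmf"`, `"gpd"`, or `"both"`.
#' @param cfg a [seg_config()].
#' @param gpd_on `"shank"` (default when a shank stream is given) or
#'   `"cane"`: stream the GPD algorithm runs on.
#' @return Named list of gait-event data.frames (`msmf`, `gpd`).
#' @export
segment_trial <- function(cane, shank = NULL, method = c("both", "msmf", "gpd"),
                          cfg = seg_config(), gpd_on = NULL) {
  method <- match.arg(method)
  out <- list()
  if (method %in% c("both", "msmf")) {
    tpl <- build_template(cane$strain, cane$sample_rate, cfg$template_strides)
    out$msmf <- detect_events_msmf(cane$strain, cane$gyro_x, cane$sample_rate,
                                   tpl, cfg)
  }
  if (method %in% c("both", "gpd")) {
    if (is.null(gpd_on)) gpd_on <- if (is.null(shank)) "cane" else "shank"
    sig <- if (gpd_on == "shank") shank$gyro_ap else cane$gyro_x
    fs <- if (gpd_on == "shank") shank$sample_rate else cane$sample_rate
    thr <- cfg$gpd_threshold
    if (identical(thr, "auto")) thr <- auto_threshold(sig)
    ps <- detect_ps_gpd(sig, fs, thr, cfg$min_stride_s)
    out$gpd <- events_from_ps_gpd(sig, fs, ps, cfg)
  }
  out
}

#' Read/write gait-event tables
#'
#' Events CSV schema: `stride,event,t_s,source` with `event` in
#' IC/TC/PS/EC and `source` in MSMF/GPD.
#'
#' @param events gait-event data.frame.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stride", "event", "t_s", "source")
  if (!all(need %in% names(df)))
    stop("events CSV must have columns stride,event,t_s,source", call. = FALSE)
  df
}
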