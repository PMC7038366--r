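#' Extract gait features from one trial
#'
#' Full single-trial pipeline: preprocess, segment the cane with MSMF,
#' optionally run GPD on the cane gyroscope for the Difference-in-IC feature
#' and on the shank stream for the gyroscope-only analogues, and return the
#' tidy feature table.
#'
#' @param cane raw [cane_recording()].
#' @param shank optional raw [shank_recording()].
#' @param cane_length metres; defaults to `cane$meta$cane_length_m`.
#' @param participant,condition labels for the output rows.
#' @param cfg a [seg_config()].
#' @param with_diff_ic run GPD on the cane gyroscope and add the `diff_ic`
#'   feature (default `TRUE`).
#' @param with_shank add shank-derived feature rows (source `"shank"`)
#'   when a shank stream is given.
#' @return Tidy feature data.frame (see [feature_table()]).
#' @export
extract_trial_features <- function(cane, shank = NULL, cane_length = NULL,
                                   participant = NA, condition = NA,
                                   cfg = seg_config(), with_diff_ic = TRUE,
                                   with_shank = FALSE) {
  pp <- preprocess(cane, shank)
  cane <- pp$cane; shank <- pp$shank
  if (is.null(cane_length)) cane_length <- cane$meta$cane_length_m
  tpl <- tryCatch(build_template(cane$strain, cane$sample_rate,
                                 cfg$template_strides),
                  error = function(e) canonical_template(cane$sample_rate))
  ev_msmf <- detect_events_msmf(cane$strain, cane$gyro_x, cane$sample_rate,
                                tpl, cfg)
  strides <- assemble_strides(ev_msmf)
  diffs <- NULL
  if (with_diff_ic) {
    thr <- cfg$gpd_threshold
    if (identical(thr, "auto")) thr <- auto_threshold(cane$gyro_x)
    ps <- detect_ps_gpd(cane$gyro_x, cane$sample_rate, thr, cfg$min_stride_s)
    ev_gpd <- events_from_ps_gpd(cane$gyro_x, cane$sample_rate, ps, cfg)
    # pairing window: the IC landmarks of the two algorithms disagree by tens
    # of milliseconds at most, so a tight window avoids stealing a distant
    # candidate when one detection is missing
    diffs <- diff_ic(ev_msmf, ev_gpd, tol = cfg$min_stride_s / 2)
  }
  out <- feature_table(strides, cane, cane_length, participant, condition,
                       diffs)
  if (with_shank && !is.null(shank)) {
    thr <- auto_threshold(shank$gyro_ap)
    ps <- detect_ps_gpd(shank$gyro_ap, shank$sample_rate, thr, cfg$min_stride_s)
    ev_sh <- events_from_ps_gpd(shank$gyro_ap, shank$sample_rate, ps, cfg)
    st_sh <- assemble_strides(ev_sh)
    st_sh <- st_sh[st_sh$valid, , drop = FALSE]
    if (nrow(st_sh)) {
      rows <- lapply(seq_len(nrow(st_sh)), function(i) {
        f <- shank_features(st_sh[i, ], shank)
        data.frame(participant = participant, condition = condition,
                   stride_index = st_sh$stride[i], feature = names(f),
                   value = unlist(f, use.names = FALSE), source = "shank",
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      out <- rbind(out, rows[!is.na(rows$value), ])
    }
  }
  out
}

#' Run a complete synthetic study end to end
#'
#' Simulate -> preprocess -> segment -> features -> statistics.  Trials are
#' generated one at a time (streams are not retained), features accumulated
#' into a tidy table, per-condition summaries computed, and - when at least
#' two conditions and two participants are present - a repeated-measures
#' ANOVA and Bonferroni pairwise comparisons run per feature on the
#' participant-mean matrices.
#'
#' @param cfg a [study_config()].
#' @param cfg_seg a [seg_config()].
#' @param with_shank include shank-derived features.
#' @param out_dir optional directory: writes `features.csv`, `summary.csv`,
#'   `report.csv`, `normalized.csv` (when a control condition is present)
#'   and `run_log.txt`.
#' @param progress print one line per trial.
#' @return List: `features` (tidy table), `summary`, `anova` (named list),
#'   `pairwise` (named list), `report`, `normalized` (or `NULL`), `truth`
#'   (per-trial truth records), `plan`.
#' @export
run_study <- function(cfg, cfg_seg = seg_config(), with_shank = FALSE,
                      out_dir = NULL, progress = FALSE) {
  plan <- study_plan(cfg)
  profs <- default_profiles()
  feats <- vector("list", nrow(plan$grid))
  truths <- vector("list", nrow(plan$grid))
  for (i in seq_len(nrow(plan$grid))) {
    row <- plan$grid[i, ]
    tr <- generate_trial(profs[[row$condition]], cfg,
                         shift = plan$shifts[row$participant, ],
                         seed = row$seed, stream_shift = row$stream_shift,
                         meta = list(participant = row$participant))
    feats[[i]] <- extract_trial_features(
      tr$cane, tr$shank, participant = row$participant,
      condition = row$condition, cfg = cfg_seg, with_shank = with_shank)
    truths[[i]] <- tr$truth
    if (progress)
      cat(sprintf("trial %d/%d (participant %d, %s): %d feature rows\n", i,
                  nrow(plan$grid), row$participant, row$condition,
                  nrow(feats[[i]])))
  }
  features <- do.call(rbind, feats)
  smry <- condition_summary(features)
  anovas <- list(); pairwise <- list()
  n_cond <- length(unique(features$condition))
  if (n_cond >= 2L && cfg$n_participants >= 2L) {
    for (f in intersect(FEATURE_NAMES, unique(features$feature))) {
      m <- try(subject_condition_matrix(smry, f), silent = TRUE)
      if (inherits(m, "try-error") || anyNA(m)) next
      anovas[[f]] <- rm_anova_oneway(m, feature = f)
      pairwise[[f]] <- bonferroni_pairwise(m, feature = f)
    }
  }
  report <- make_report(smry, anovas, pairwise)
  normalized <- if ("control" %in% features$condition)
    normalize_to_control(smry) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(smry, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    if (!is.null(normalized))
      utils::write.csv(normalized, file.path(out_dir, "normalized.csv"),
                       row.names = FALSE)
    writeLines(c(sprintf("seed: %d", cfg$seed),
                 sprintf("participants: %d", cfg$n_participants),
                 sprintf("strides_per_trial: %d", cfg$strides_per_trial),
                 sprintf("conditions: %s", paste(cfg$conditions, collapse = ", ")),
                 sprintf("noise_sd_strain: %g", cfg$noise_sd_strain),
                 sprintf("noise_sd_gyro: %g", cfg$noise_sd_gyro)),
               file.path(out_dir, "run_log.txt"))
  }
  list(features = features, summary = smry, anova = anovas,
       pairwise = pairwise, report = report, normalized = normalized,
       truth = truths, plan = plan$grid)
}

#' Grand mean of a feature over a feature table
#'
#' @param features tidy feature table.
#' @param feature feature name.
#' @param source source stream.
#' @return Mean value over all strides.
#' @export
grand_mean <- function(features, feature, source = "cane") {
  v <- features$value[features$feature == feature & features$source == source]
  mean(v)
}
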