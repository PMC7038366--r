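# build a minimal preprocessed-style recording with analytic shapes
analytic_cane <- function(fs = 231, stance = 0.6, swing = 0.6,
                          v_peak = 200, v_at = 0.25,
                          s_peak = 150, s_at = 0.35, lead = 1) {
  t <- seq(0, lead + stance + swing + 1, by = 1 / fs)
  ic <- lead; tc <- ic + stance; ec <- tc + swing
  strain <- rep(-2, length(t))
  i <- t >= ic & t <= tc
  strain[i] <- (s_peak + 2) * sin(pi / 2 * pmin((t[i] - ic) / s_at,
                                                (tc - t[i]) / (stance - s_at)))^2 - 2
  g <- numeric(length(t))
  i <- t > tc & t <= ec
  g[i] <- v_peak * sin(pi / 2 * pmin((t[i] - tc) / v_at,
                                     (ec - t[i]) / (swing - v_at)))^2
  rec <- cane_recording(time = t, strain = strain, gyro_x = g,
                        sample_rate = fs, meta = list(cane_length_m = 0.9))
  stride <- data.frame(stride = 1L, ic = ic, tc = tc, ps = tc + v_at, ec = ec,
                       source = "MSMF", valid = TRUE, reason = "")
  list(rec = rec, stride = stride)
}

test_that("stride_features recovers analytic construction parameters", {
  a <- analytic_cane()
  f <- stride_features(a$stride, a$rec)
  smp <- 1000 / 231
  expect_equal(f$max_pv_swing, 200, tolerance = 0.01)
  expect_lt(abs(f$max_pv_time_wrt_tc - 250), smp)
  expect_equal(f$swing_stance_ratio, 1.0)
  expect_equal(f$max_strain, 150, tolerance = 0.01)
  expect_lt(abs(f$max_strain_time_wrt_ic - 350), smp)
  # ratio equals the event-based ratio identically
  expect_equal(f$swing_stance_ratio,
               (a$stride$ec - a$stride$tc) / (a$stride$tc - a$stride$ic),
               tolerance = 1e-12)
})

test_that("stride_features refuses invalid strides", {
  a <- analytic_cane()
  bad <- a$stride; bad$valid <- FALSE; bad$reason <- "order"
  expect_error(stride_features(bad, a$rec), "not valid")
})

test_that("pendulum stride length matches the closed form", {
  fs <- 231
  t <- seq(0, 3, by = 1 / fs)
  stride <- list(tc = 1, ec = 1.5)
  g0 <- numeric(length(t))
  expect_equal(stride_length_pendulum(g0, stride, fs, 0.9), 0)
  gc <- ifelse(t > 1 & t <= 1.5, 90, 0)   # constant 90 deg/s over 0.5 s
  got <- stride_length_pendulum(gc, stride, fs, 0.9)
  # step edges lose half a sample each under the in-phase trapezoid rule
  expect_equal(got, 2 * 0.9 * sin(22.5 * pi / 180), tolerance = 0.015)
  expect_error(stride_length_pendulum(gc, stride, fs, 0), "> 0")
  # negative sweep clamps at zero
  expect_equal(stride_length_pendulum(-gc, stride, fs, 0.9), 0)
})

test_that("pendulum estimator inverts the generator's sweep construction", {
  tr <- clean_trial(n_strides = 5)
  pp <- preprocess(tr$cane, tr$shank)
  ev <- tr$truth$events
  dr <- tr$truth$params
  for (k in 2:4) {
    stride <- list(tc = ev$t_s[ev$stream == "cane" & ev$event == "TC"][k],
                   ec = ev$t_s[ev$stream == "cane" & ev$event == "EC"][k])
    sl <- stride_length_pendulum(pp$cane$gyro_x, stride, 231, 0.9)
    expect_lt(abs(sl - dr$stride_len_achieved[k]) / 1.1, 0.01)
  }
})

test_that("diff_ic pairs nearest landmarks and reports the signed lag", {
  ev <- gait_events_df(1:3, rep("IC", 3), c(1, 2, 3), "MSMF")
  expect_equal(diff_ic(ev, ev)$diff_ms, c(0, 0, 0))
  gpd <- ev; gpd$t_s <- gpd$t_s + 0.0126
  d <- diff_ic(ev, gpd)
  expect_equal(d$diff_ms, rep(-12.6, 3), tolerance = 1e-9)
  # landmarks beyond the tolerance stay unpaired
  far <- ev; far$t_s <- far$t_s + 5
  d2 <- diff_ic(ev, far, tol = 0.2)
  expect_length(d2$diff_ms, 0L)
  expect_length(d2$unpaired_msmf, 3L)
})

test_that("clean-trial diff_ic reproduces the drawn GPD lag", {
  tr <- clean_trial(n_strides = 6)
  pp <- preprocess(tr$cane, tr$shank)
  seg <- segment_trial(pp$cane, method = "both", gpd_on = "cane")
  d <- diff_ic(seg$msmf, seg$gpd, tol = 0.2)
  expect_gte(length(d$diff_ms), 5L)
  expect_lt(abs(mean(d$diff_ms) - (-12.6)), 1000 / 231)  # within one sample
})

test_that("shank features carry gyro members only", {
  tr <- clean_trial(n_strides = 5)
  pp <- preprocess(tr$cane, tr$shank)
  thr <- auto_threshold(pp$shank$gyro_ap)
  ps <- detect_ps_gpd(pp$shank$gyro_ap, 100, thr)
  st <- assemble_strides(events_from_ps_gpd(pp$shank$gyro_ap, 100, ps))
  st <- st[st$valid, ]
  f <- shank_features(st[2, ], pp$shank)
  expect_true(is.na(f$max_strain) && is.na(f$max_strain_time_wrt_ic))
  expect_equal(f$max_pv_swing, 0.9 * 246.5, tolerance = 0.02 * 246.5)
  expect_gt(f$swing_stance_ratio, 0)
})

test_that("condition_summary aggregates strides and participants", {
  tab <- data.frame(
    participant = c(1, 1, 2, 2), condition = "control",
    stride_index = c(1, 2, 1, 2), feature = "max_strain",
    value = c(100, 110, 120, 130), source = "cane")
  s <- condition_summary(tab)
  expect_equal(s$mean, 115)
  expect_equal(s$sd, stats::sd(c(100, 110, 120, 130)))
  pm <- attr(s, "participant_means")
  expect_equal(sort(pm$mean), c(105, 125))
  single <- condition_summary(tab[1, ])
  expect_equal(single$sd, 0)

  m <- subject_condition_matrix(s, "max_strain")
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(unname(m[, 1]), c(105, 125))
  expect_error(condition_summary(tab[0, ]), "empty")
})

test_that("every feature row traces to one valid stride", {
  tr <- noisy_trial(n_strides = 8, seed = 19)
  ft <- extract_trial_features(tr$cane, tr$shank, participant = 1,
                               condition = "control")
  per_stride <- table(ft$stride_index[ft$feature != "diff_ic"])
  expect_true(all(per_stride == 7L))   # 7 cane features per stride
  expect_true(all(ft$feature %in% c("max_pv_swing", "max_pv_stance",
                                    "max_pv_time_wrt_tc", "swing_stance_ratio",
                                    "max_strain", "max_strain_time_wrt_ic",
                                    "stride_length", "diff_ic")))
})

test_that("feature recovery matches drawn parameters on a clean trial", {
  tr <- clean_trial(n_strides = 6)
  ft <- extract_trial_features(tr$cane, tr$shank, participant = 1,
                               condition = "control")
  gm <- function(f) mean(ft$value[ft$feature == f & ft$source == "cane"])
  smp <- 1000 / 231
  expect_lt(abs(gm("max_pv_swing") - 246.5) / 246.5, 0.001 + 0.01)
  expect_lt(abs(gm("max_pv_stance") - 156.4) / 156.4, 0.011)
  expect_lt(abs(gm("max_pv_time_wrt_tc") - 258), smp)
  expect_lt(abs(gm("swing_stance_ratio") - 1), 0.02)
  expect_lt(abs(gm("max_strain") - 110.6) / 110.6, 0.011)
  expect_lt(abs(gm("max_strain_time_wrt_ic") - 361.9), smp)
  expect_lt(abs(gm("stride_length") - 1.1) / 1.1, 0.01)
})
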