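test_that("detect_ps_gpd finds one peak per supra-threshold excursion", {
  fs <- 100
  t <- (0:999) / fs
  bump <- function(c0, w, a) ifelse(abs(t - c0) < w, a * cos(pi / 2 * (t - c0) / w)^2, 0)
  g <- bump(2, 0.3, 100)
  ps <- detect_ps_gpd(g, fs, threshold = 50)
  expect_identical(ps, which.max(g))            # brute-force argmax oracle

  expect_length(detect_ps_gpd(g, fs, threshold = 150), 0L)

  g2 <- bump(2, 0.3, 100) + bump(3, 0.3, 80)
  ps2 <- detect_ps_gpd(g2, fs, threshold = 50)
  expect_length(ps2, 2L)
  expect_true(all(diff(ps2) > 0))
  expect_error(detect_ps_gpd(g, fs, threshold = 0), "> 0")
})

test_that("auto_threshold is homogeneous and rejects non-positive signals", {
  set.seed(3)
  g <- abs(rnorm(1000)) * 50
  expect_equal(auto_threshold(2 * g), 2 * auto_threshold(g), tolerance = 1e-9)
  expect_error(auto_threshold(-abs(rnorm(100)) - 1), "positive")
})

test_that("auto threshold separates shank stance and swing activity", {
  tr <- noisy_trial(n_strides = 15, seed = 41)
  pp <- preprocess(tr$cane, tr$shank)
  thr <- auto_threshold(pp$shank$gyro_ap)
  v_sw <- mean(tr$truth$params$shank_v)
  expect_gt(thr, 0.2 * v_sw)    # above the stance-lobe amplitude
  expect_lt(thr, v_sw)          # below the swing peak
})

test_that("GPD recovers shank events within one sample on clean data", {
  tr <- clean_trial(n_strides = 6)
  pp <- preprocess(tr$cane, tr$shank)
  thr <- auto_threshold(pp$shank$gyro_ap)
  ps <- detect_ps_gpd(pp$shank$gyro_ap, 100, thr)
  ev <- events_from_ps_gpd(pp$shank$gyro_ap, 100, ps)
  tm <- expect_events_close(ev, tr$truth$events, "shank", 1 / 100)
  expect_equal(nrow(tm), 6L * 4L)
  # EC of cycle k is exactly the IC of cycle k+1
  st <- assemble_strides(ev)
  expect_identical(st$ec[-nrow(st)], st$ic[-1L])
})

test_that("a peak with no bracketing minimum yields no cycle", {
  fs <- 100
  t <- (0:599) / fs
  g <- ifelse(abs(t - 3) < 0.3, 100 * cos(pi / 2 * (t - 3) / 0.3)^2, 0)
  ps <- detect_ps_gpd(g, fs, 50)
  ev <- events_from_ps_gpd(g, fs, ps)
  expect_equal(nrow(ev), 0L)
})

test_that("build_template matches the true loading bump", {
  tr <- clean_trial(n_strides = 8)
  pp <- preprocess(tr$cane, tr$shank)
  tpl <- build_template(pp$cane$strain, 231)
  # direct correlation oracle against one true bump
  ev <- tr$truth$events
  ic2 <- ev$t_s[ev$stream == "cane" & ev$event == "IC"][2]
  tc2 <- ev$t_s[ev$stream == "cane" & ev$event == "TC"][2]
  idx <- which(pp$cane$time >= ic2 & pp$cane$time <= tc2)
  bump <- stats::approx(seq_along(idx), pp$cane$strain[idx],
                        xout = seq(1, length(idx), length.out = length(tpl)))$y
  expect_gt(stats::cor(tpl, bump), 0.99)
  # template length tracks the loading-phase duration
  expect_lt(abs(length(tpl) / 231 - 0.65), 0.1 * 0.65)
  expect_error(build_template(pp$cane$strain, 231, n = 100L), "bumps")
})

test_that("msmf_trace is a bounded normalized correlation", {
  set.seed(8)
  tpl <- sin(pi * (1:50) / 51)^2
  x <- numeric(500)
  x[201:250] <- tpl
  tr <- msmf_trace(x + rnorm(500, 0, 1e-8), tpl)
  expect_equal(which.max(tr), 201L)
  expect_gt(max(tr), 0.9999)
  expect_lt(max(abs(tr)), 1 + 1e-9)
  trneg <- msmf_trace(-x + rnorm(500, 0, 1e-8), tpl)
  expect_lt(trneg[201], 0)
  expect_error(msmf_trace(x, numeric(0)), "template")
  expect_error(msmf_trace(x, rep(1, 10)), "zero-energy")
})

test_that("MSMF recovers every clean stride within one sample", {
  tr <- clean_trial(n_strides = 6)
  pp <- preprocess(tr$cane, tr$shank)
  tpl <- build_template(pp$cane$strain, 231)
  ev <- detect_events_msmf(pp$cane$strain, pp$cane$gyro_x, 231, tpl)
  tm <- expect_events_close(ev, tr$truth$events, "cane", 1 / 231)
  expect_equal(nrow(tm), 6L * 4L)      # precision = recall = 1
})

test_that("MSMF returns nothing without a similarity peak above threshold", {
  tpl <- sin(pi * (1:80) / 81)^2
  flat <- rep(-2, 2000)
  ev <- detect_events_msmf(flat, numeric(2000), 231, tpl)
  expect_equal(nrow(ev), 0L)
  # anti-correlated strain: trace stays below the 50% similarity threshold
  x <- rep(-2, 2000)
  x[501:580] <- -2 - 40 * tpl / max(tpl)
  ev2 <- detect_events_msmf(x, numeric(2000), 231, tpl)
  expect_equal(nrow(ev2), 0L)
})

test_that("MSMF detections are invariant to positive strain scaling", {
  tr <- clean_trial(n_strides = 5)
  pp <- preprocess(tr$cane, tr$shank)
  tpl <- build_template(pp$cane$strain, 231)
  a <- detect_events_msmf(pp$cane$strain, pp$cane$gyro_x, 231, tpl)
  b <- detect_events_msmf(7.3 * pp$cane$strain, pp$cane$gyro_x, 231,
                          build_template(7.3 * pp$cane$strain, 231))
  expect_equal(a$t_s, b$t_s, tolerance = 1e-9)
})

test_that("event order IC < TC < PS < EC holds for every valid stride", {
  for (cond in c("control", "upstairs", "plantarflexion")) {
    tr <- noisy_trial(cond, n_strides = 10, seed = 17)
    pp <- preprocess(tr$cane, tr$shank)
    tpl <- build_template(pp$cane$strain, 231)
    st <- assemble_strides(detect_events_msmf(pp$cane$strain, pp$cane$gyro_x,
                                              231, tpl))
    st <- st[st$valid, ]
    expect_true(all(st$ic < st$tc & st$tc < st$ps & st$ps < st$ec))
  }
})

test_that("assemble_strides flags incomplete and misordered groups", {
  ok <- gait_events_df(rep(1:2, each = 4), rep(c("IC", "TC", "PS", "EC"), 2),
                       c(0, 0.5, 0.8, 1.2, 1.2, 1.7, 2.0, 2.4), "MSMF")
  st <- assemble_strides(ok)
  expect_equal(sum(st$valid), 2L)

  partial <- ok[1:7, ]                          # missing final EC
  st2 <- assemble_strides(partial)
  expect_true(st2$valid[1] && !st2$valid[2])
  expect_equal(st2$reason[2], "incomplete")

  bad <- ok
  bad$t_s[bad$stride == 1 & bad$event == "PS"] <- 0.3   # PS before TC
  st3 <- assemble_strides(bad)
  expect_false(st3$valid[1])
  expect_equal(st3$reason[1], "order")
})

test_that("sync_offset recovers the injected inter-stream shift", {
  tr <- clean_trial(n_strides = 5, seed = 60)
  tr2 <- generate_trial(zero_sd_profile(default_profiles()$control),
                        study_config(1, 5, "control", seed = 1,
                                     noise_sd_strain = 0, noise_sd_gyro = 0),
                        seed = 60, stream_shift = 2.0)
  pp2 <- preprocess(tr2$cane, tr2$shank)
  expect_lt(abs(sync_offset(pp2$cane, pp2$shank) - 2.0), 0.010)

  tr0 <- generate_trial(zero_sd_profile(default_profiles()$control),
                        study_config(1, 5, "control", seed = 1,
                                     noise_sd_strain = 0, noise_sd_gyro = 0),
                        seed = 60, stream_shift = 0)
  pp0 <- preprocess(tr0$cane, tr0$shank)
  expect_lt(abs(sync_offset(pp0$cane, pp0$shank)), 0.010)

  flat <- shank_recording(time = pp0$shank$time,
                          gyro_ap = numeric(length(pp0$shank$time)))
  expect_error(sync_offset(pp0$cane, flat), "synchronization")
})

test_that("events CSV round-trips", {
  tr <- clean_trial(n_strides = 4)
  pp <- preprocess(tr$cane, tr$shank)
  ev <- segment_trial(pp$cane, pp$shank, method = "both")
  f <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev$msmf, f)
  back <- read_events_csv(f)
  expect_equal(back$t_s, ev$msmf$t_s, tolerance = 1e-9)
  expect_setequal(unique(back$event), c("IC", "TC", "PS", "EC"))
})
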