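test_that("default profiles carry the published condition summaries", {
  p <- default_profiles()
  expect_length(p, 11L)
  expect_setequal(names(p), c("control", "plantarflexion", "dorsiflexion",
                              "uphill", "downhill", "upstairs", "downstairs",
                              "fogged_glasses", "eyes_closed", "long_cane",
                              "short_cane"))
  expect_equal(unname(p$control$v_swing["mean"]), 246.5)
  expect_equal(unname(p$control$v_stance["sd"]), 33.3)
  expect_equal(unname(p$upstairs$stride_length_m["mean"]), 0.3)
  expect_equal(unname(p$control$gpd_ic_lag_s["mean"]), 0.0126)
  expect_equal(unname(p$downstairs$gpd_ic_lag_s["mean"]), 0.0633)
  expect_equal(unname(p$dorsiflexion$strain_peak["mean"]), 188)
  expect_equal(p$long_cane$cane_length_m - p$control$cane_length_m, 0.0508)
  expect_equal(p$control$cane_length_m - p$short_cane$cane_length_m, 0.0508)
  for (pr in p) {
    expect_gt(pr$v_swing["mean"], pr$v_stance["mean"])
    expect_lt(pr$ps_offset_s["mean"], pr$swing_s["mean"])
    expect_lt(pr$strain_peak_offset_s["mean"], pr$stance_s["mean"])
    expect_gte(pr$stride_length_m["mean"], 0)
    expect_gt(pr$stance_s["mean"], 0)
  }
})

test_that("synth_stride realizes the pendulum sweep of its draw", {
  pr <- default_profiles()$control
  st <- synth_stride(pr)
  ev <- st$events$cane
  idx <- which(st$t > ev["tc"] & st$t <= ev["ec"])
  theta_meas <- sum(diff(st$t[idx]) *
                      (st$gyro_ap[idx][-1] + st$gyro_ap[idx][-length(idx)]) / 2)
  theta_want <- 2 * asin(1.1 / (2 * 0.9)) * 180 / pi
  expect_lt(abs(theta_meas - theta_want), 0.5)

  # zero stride length: swing-phase integral vanishes
  d0 <- st$params[1, seq_len(13)]
  d0$stride_len <- 0
  st0 <- synth_stride(pr, draw = d0)
  idx0 <- which(st0$t > st0$events$cane["tc"] & st0$t <= st0$events$cane["ec"])
  th0 <- sum(diff(st0$t[idx0]) *
               (st0$gyro_ap[idx0][-1] + st0$gyro_ap[idx0][-length(idx0)]) / 2)
  expect_lt(abs(th0) * pi / 180, 1e-6)
})

test_that("synth_stride places the strain apex at IC + offset", {
  pr <- default_profiles()$control
  st <- synth_stride(pr)
  apex_t <- st$t[which.max(st$strain)]
  expect_lt(abs(apex_t - (st$events$cane["ic"] + 0.3619)), 0.5 / 231)
  expect_equal(max(st$strain), 110.6, tolerance = 0.01)
})

test_that("synth_stride rejects an unrealizable sweep", {
  pr <- default_profiles()$control
  d <- synth_stride(pr)$params[1, seq_len(13)]
  d$v_swing <- 16; d$v_stance <- 10; d$stride_len <- 1.7
  expect_error(synth_stride(pr, draw = d), "unsatisfiable")
})

test_that("generate_trial is fully reproducible from its seed", {
  cfg <- study_config(1, 6, "control", seed = 1)
  a <- generate_trial(default_profiles()$control, cfg, seed = 77)
  b <- generate_trial(default_profiles()$control, cfg, seed = 77)
  expect_identical(a$cane$strain, b$cane$strain)
  expect_identical(a$cane$gyro_x, b$cane$gyro_x)
  expect_identical(a$shank$gyro_ap, b$shank$gyro_ap)
  expect_identical(a$truth, b$truth)
  # and byte-for-byte through CSV
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_cane_log(a$cane, fa); write_cane_log(b$cane, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("trial truth has 4 events per stride per stream, strictly ordered", {
  tr <- noisy_trial(n_strides = 7, seed = 31)
  ev <- tr$truth$events
  for (s in c("cane", "shank")) {
    es <- ev[ev$stream == s, ]
    expect_equal(nrow(es), 4L * 7L)
    for (k in unique(es$stride)) {
      g <- es[es$stride == k, ]
      tt <- stats::setNames(g$t_s, g$event)
      expect_true(tt["IC"] < tt["TC"] && tt["TC"] < tt["PS"] &&
                    tt["PS"] < tt["EC"])
      if (k < max(es$stride))
        expect_equal(unname(tt["EC"]),
                     es$t_s[es$stride == k + 1 & es$event == "IC"])
    }
  }
})

test_that("degenerate generator reproduces the condition means exactly", {
  tr <- clean_trial("control", n_strides = 5)
  pp <- preprocess(tr$cane, tr$shank)
  ev <- tr$truth$events
  ic <- ev$t_s[ev$stream == "cane" & ev$event == "IC"]
  tc <- ev$t_s[ev$stream == "cane" & ev$event == "TC"]
  for (k in 2:4) {
    idx <- which(pp$cane$time >= ic[k] & pp$cane$time <= tc[k])
    expect_equal(max(pp$cane$strain[idx]), 110.6, tolerance = 0.1)
  }
})

test_that("with no between-participant variance the shift has no effect", {
  pr <- default_profiles()$control
  shift <- stats::setNames(rep(3, length(canegait:::SHIFT_FIELDS)),
                           canegait:::SHIFT_FIELDS)
  set.seed(1); a <- draw_stride_params(pr, 20, shift, sd_scale = 0)
  set.seed(1); b <- draw_stride_params(pr, 20, NULL, sd_scale = 0)
  expect_identical(a, b)
})

test_that("participant shifts are shared across conditions", {
  # with all variance between participants, the standardized deviation from
  # the condition mean is the same number in every condition
  profs <- default_profiles()
  shift <- participant_shifts(study_config(n_participants = 4, seed = 9))[2, ]
  set.seed(2); d1 <- draw_stride_params(profs$control, 5, shift, sd_scale = 1)
  set.seed(3); d2 <- draw_stride_params(profs$dorsiflexion, 5, shift, sd_scale = 1)
  z1 <- (d1$strain_peak[1] - 110.6) / 57.7
  z2 <- (d2$strain_peak[1] - 188) / 83
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("generate_study produces the full participant x condition grid", {
  cfg <- study_config(2, 3, conditions = c("control", "uphill"), seed = 5)
  st <- generate_study(cfg, keep_streams = FALSE)
  expect_equal(nrow(st$plan), 4L)
  expect_length(st$trials, 4L)
  expect_setequal(unique(st$plan$condition), c("control", "uphill"))
})

test_that("drawn swing velocities concentrate on the published mean", {
  cfg <- study_config(30, 40, "control", seed = 8)
  shifts <- participant_shifts(cfg)
  pr <- default_profiles()$control
  set.seed(cfg$seed)
  v <- unlist(lapply(seq_len(30), function(p)
    draw_stride_params(pr, 40, shifts[p, ])$v_swing))
  expect_lt(abs(mean(v) - 246.5), 2 * 55.5 / sqrt(1200))
})

test_that("study config round-trips through YAML", {
  cfg <- study_config(5, 12, c("control", "upstairs"), seed = 3,
                      noise_sd_strain = 0.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, f)
  back <- read_study_config(f)
  expect_equal(back$n_participants, 5L)
  expect_equal(back$conditions, c("control", "upstairs"))
  expect_equal(back$noise_sd_strain, 0.5)
})
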