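# Shared fixtures: all synthetic, built in code at test time.

# profile with all between/within SDs zeroed (every stride at the condition
# means); used for noise-free oracle comparisons
zero_sd_profile <- function(profile) {
  for (f in setdiff(names(profile), c("name", "cane_length_m")))
    profile[[f]]["sd"] <- 0
  profile
}

# small clean (noise-free, zero-SD) trial of a given condition
clean_trial <- function(condition = "control", n_strides = 6, seed = 100) {
  cfg <- study_config(n_participants = 1, strides_per_trial = n_strides,
                      conditions = condition, seed = 1,
                      noise_sd_strain = 0, noise_sd_gyro = 0)
  generate_trial(zero_sd_profile(default_profiles()[[condition]]), cfg,
                 seed = seed)
}

# default-noise trial with drawn per-stride parameters
noisy_trial <- function(condition = "control", n_strides = 20, seed = 100,
                        stream_shift = NULL) {
  cfg <- study_config(n_participants = 1, strides_per_trial = n_strides,
                      conditions = condition, seed = 1)
  generate_trial(default_profiles()[[condition]], cfg, seed = seed,
                 stream_shift = stream_shift)
}

expect_events_close <- function(detected, truth_events, stream, tol_s) {
  tm <- merge(detected, truth_events[truth_events$stream == stream, ],
              by = c("stride", "event"))
  expect_gt(nrow(tm), 0)
  expect_lt(max(abs(tm$t_s.x - tm$t_s.y)), tol_s)
  invisible(tm)
}

gait_events_df <- function(stride, event, t_s, source) {
  data.frame(stride = as.integer(stride), event = event, t_s = t_s,
             source = source, stringsAsFactors = FALSE)
}
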