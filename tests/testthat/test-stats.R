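test_that("repeated-measures ANOVA matches hand-derived cases", {
  # identical rows across conditions: no condition effect at all
  m0 <- matrix(rep(c(1, 2, 3), 2), ncol = 2)
  expect_equal(rm_anova_oneway(m0)$F, 0)

  # 3 subjects x 2 conditions (1,2),(2,4),(3,3): F equals the squared paired
  # t statistic, t^2 = 3 (hand computation)
  m <- rbind(c(1, 2), c(2, 4), c(3, 3))
  a <- rm_anova_oneway(m)
  expect_equal(a$F, 3.0, tolerance = 1e-12)
  expect_equal(a$df_condition, 1L)
  expect_equal(a$df_error, 2L)

  # subject effects are absorbed
  m2 <- m + c(10, -5, 100)
  expect_equal(rm_anova_oneway(m2)$F, a$F, tolerance = 1e-9)
})

test_that("ANOVA invariances and sum-of-squares conservation hold", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 4, mean = 50, sd = 5), nrow = 8)
    a <- rm_anova_oneway(m)
    ss_tot <- sum((m - mean(m))^2)
    expect_lt(abs(a$ss_condition + a$ss_subject + a$ss_error - ss_tot) /
                ss_tot, 1e-9)
    expect_equal(rm_anova_oneway(m + 17.3)$F, a$F, tolerance = 1e-9)
    expect_equal(rm_anova_oneway(m * -2.5)$F, a$F, tolerance = 1e-9)
    expect_equal(rm_anova_oneway(m + rnorm(8))$F, a$F, tolerance = 1e-9)
  }
})

test_that("F equals the squared paired t statistic for two conditions", {
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(rnorm(12 * 2, 10, 3), ncol = 2)
    a <- rm_anova_oneway(m)
    tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
    expect_lt(abs(a$F - tt$statistic^2), 1e-9)
    expect_lt(abs(a$p - tt$p.value), 1e-9)
  }
})

test_that("ANOVA agrees with the aov() within-subject decomposition", {
  set.seed(13)
  n <- 6; k <- 4
  m <- matrix(rnorm(n * k, 100, 10), n, k) + rnorm(n, 0, 5)
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     cond = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ cond + Error(subject), data = long)
  ref <- summary(fit)[["Error: Within"]][[1]]
  a <- rm_anova_oneway(m)
  expect_equal(a$F, ref["cond", "F value"], tolerance = 1e-9)
  expect_equal(a$p, ref["cond", "Pr(>F)"], tolerance = 1e-9)
})

test_that("ANOVA rejects incomplete input", {
  m <- matrix(rnorm(6), 3); m[2, 1] <- NA
  expect_error(rm_anova_oneway(m), "missing cells")
  expect_error(rm_anova_oneway(matrix(1:2, 1)), "at least 2")
})

test_that("Bonferroni pairwise comparisons follow the closed form", {
  set.seed(14)
  m2 <- matrix(rnorm(10 * 2, 5), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pw2 <- bonferroni_pairwise(m2)
  expect_equal(pw2$p_adj, pw2$p_raw)    # single pair: no correction

  m3 <- matrix(rnorm(10 * 3, 5), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  pw3 <- bonferroni_pairwise(m3)
  expect_equal(nrow(pw3), 3L)
  expect_equal(pw3$p_adj, pmin(pw3$p_raw * 3, 1))
  expect_equal(pw3$p_adj,
               unname(stats::p.adjust(pw3$p_raw, "bonferroni")),
               tolerance = 1e-12)
  expect_true(all(pw3$p_adj >= pw3$p_raw - 1e-15 & pw3$p_adj <= 1))
  expect_identical(pw3$significant, !is.na(pw3$p_adj) & pw3$p_adj < 0.05)
})

test_that("zero-variance differences are degenerate, never significant", {
  m <- cbind(a = 1:6, b = 1:6 + 2, c = rnorm(6))
  pw <- bonferroni_pairwise(m)
  ab <- pw[pw$condition_a == "a" & pw$condition_b == "b", ]
  expect_true(ab$degenerate)
  expect_false(ab$significant)
})

test_that("normalize_to_control divides by the control mean", {
  s <- data.frame(condition = c("control", "dorsi", "control", "dorsi"),
                  feature = rep(c("max_pv_swing", "max_strain"), each = 2),
                  source = "cane",
                  mean = c(246.5, 123.25, 110, 0), sd = 1, n = 10)
  # move the zero mean to the control row of max_strain
  s$mean <- c(246.5, 123.25, 0, 140)
  nz <- normalize_to_control(s)
  expect_equal(nz$ratio[nz$condition == "control" & nz$feature == "max_pv_swing"], 1)
  expect_equal(nz$ratio[nz$condition == "dorsi" & nz$feature == "max_pv_swing"], 0.5)
  expect_true(nz$undefined[nz$feature == "max_strain" & nz$condition == "dorsi"])
  expect_error(normalize_to_control(s[s$condition == "dorsi", ]), "control")
})

test_that("make_report renders mean +/- sd cells with significance stars", {
  s <- data.frame(condition = "control", feature = "max_pv_swing",
                  source = "cane", mean = 246.5, sd = 55.5, n = 100)
  r1 <- make_report(s)
  expect_equal(nrow(r1), 1L)
  expect_match(r1$control, "\\(246.5 ± 55.5\\)")
  expect_false(grepl("\\*", r1$control))

  s3 <- rbind(s,
              transform(s, condition = "plant", mean = 228.3, sd = 73.8),
              transform(s, condition = "dorsi", mean = 204.9, sd = 61.6))
  pw <- data.frame(feature = "max_pv_swing",
                   condition_a = c("control", "control", "plant"),
                   condition_b = c("plant", "dorsi", "dorsi"),
                   mean_diff = 1, p_raw = 0.001, p_adj = 0.003,
                   significant = c(TRUE, TRUE, TRUE), degenerate = FALSE)
  a <- rm_anova_oneway(matrix(rnorm(30), 10), feature = "max_pv_swing")
  r3 <- make_report(s3, anovas = list(max_pv_swing = a),
                    pairwise = list(max_pv_swing = pw))
  expect_match(r3$plant, "\\*")
  expect_match(r3$dorsi, "\\*\\*")
})

test_that("cane and shank trends share a sign for dorsiflexion vs control", {
  cfg <- study_config(4, 10, c("control", "dorsiflexion"), seed = 6)
  res <- run_study(cfg, with_shank = TRUE)
  nz <- res$normalized
  for (src in c("cane", "shank")) {
    r <- nz$ratio[nz$condition == "dorsiflexion" & nz$source == src &
                    nz$feature == "max_pv_swing"]
    expect_lt(r, 1)   # both streams see the dorsiflexion slow-down
  }
})
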