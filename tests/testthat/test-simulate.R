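test_that("zero-noise U-turn lobes integrate to pi within 1%", {
  p <- zero_noise_profile()
  s <- simulate_session(p, build_circuit(laps = 2), "normal", seed = 1)
  # independent oracle: trapezoidal integration over each contiguous
  # suprathreshold excursion of the raw yaw-rate channel
  gz <- s$imu$gz
  t <- s$imu$t
  on <- abs(gz) > 0.01
  grp <- cumsum(c(TRUE, diff(on) != 0))
  angles <- vapply(split(seq_along(gz), grp), function(idx) {
    if (!on[idx[1]] || length(idx) < 2) return(NA_real_)
    sum((gz[idx[-1]] + gz[idx[-length(idx)]]) / 2 * diff(t[idx]))
  }, numeric(1))
  uturn_angles <- angles[!is.na(angles) & abs(angles) > 2]
  expect_length(uturn_angles, 4)  # 2 U-turns per lap x 2 laps
  expect_true(all(abs(abs(uturn_angles) - pi) / pi < 0.01))
})

test_that("sessions are byte-identical for identical inputs and seed", {
  p <- subject_profile("d", "MCI")
  circ <- build_circuit(laps = 1)
  s1 <- simulate_session(p, circ, "aggressive", seed = 7)
  s2 <- simulate_session(p, circ, "aggressive", seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_session(p, circ, "aggressive", seed = 8)
  expect_false(identical(s1$imu, s3$imu))
})

test_that("default protocol completes 10 full heading cycles and 540 m laps", {
  p <- zero_noise_profile()
  s <- simulate_session(p, build_circuit(), "normal", seed = 3)
  # independent heading integration
  dt <- median(diff(s$imu$t))
  total <- sum(s$imu$gz) * dt
  expect_equal(floor(total / (2 * pi) + 1e-6), 10)
  expect_equal(count_laps(s), 10L)
  expect_equal(path_length(s) / 10, 540, tolerance = 1e-9)
})

test_that("nominal sampling rates are exact and spans aligned", {
  p <- subject_profile("r", "Healthy")
  s <- simulate_session(p, build_circuit(laps = 1), "normal", seed = 5)
  expect_equal(median(diff(s$imu$t)), 0.1)
  expect_equal(median(diff(s$gps$t)), 1.0)
  expect_true(all(diff(s$imu$t) > 0))
  expect_true(all(diff(s$gps$t) > 0))
  # channel groups cover the same span within one GPS period
  expect_lte(abs(max(s$gps$t) - max(s$imu$t)), 1.0)
  expect_lte(abs(min(s$gps$t) - min(s$imu$t)), 1.0)
})

test_that("per-lap integrated heading matches the design within 2% at default noise", {
  p <- subject_profile("n", "Healthy")
  s <- simulate_session(p, build_circuit(laps = 5), "normal", seed = 9)
  dt <- median(diff(s$imu$t))
  total <- sum(s$imu$gz) * dt
  expect_lt(abs(total - 5 * 2 * pi) / (5 * 2 * pi), 0.02)
})

test_that("default cohort reproduces the 21-subject roster with 42 sessions", {
  coh <- default_cohort()
  expect_equal(nrow(coh$roster), 21)
  expect_equal(sum(coh$roster$status == "Healthy"), 13)
  expect_equal(sum(coh$roster$status == "MCI"), 8)
  expect_length(coh$sessions, 42)
  conds <- vapply(coh$sessions, `[[`, "", "condition")
  expect_equal(sum(conds == "normal"), 21)
  expect_equal(sum(conds == "aggressive"), 21)
})

test_that("empty cohort request yields empty roster and session list", {
  coh <- generate_cohort(cohort_config(n_healthy = 0, n_mci = 0), seed = 1)
  expect_equal(nrow(coh$roster), 0)
  expect_length(coh$sessions, 0)
})

test_that("effect_size = 0 makes status-conditional kinematics indistinguishable", {
  cfg <- cohort_config(effect_size = 0, n_healthy = 100, n_mci = 100,
                       conditions = character(0))  # profiles only
  coh <- generate_cohort(cfg, seed = 11)
  peak <- vapply(coh$profiles, function(p) p$styles$normal$peak_yaw_90,
                 numeric(1))
  status <- coh$roster$status
  d <- abs(mean(peak[status == "Healthy"]) - mean(peak[status == "MCI"]))
  se <- sqrt(var(peak[status == "Healthy"]) / 100 +
             var(peak[status == "MCI"]) / 100)
  expect_lt(d, 2 * se)
})

test_that("status effect on mean turn speed is monotone in effect_size", {
  gap <- vapply(c(0, 1, 2), function(es) {
    cfg <- cohort_config(effect_size = es, n_healthy = 100, n_mci = 100,
                         conditions = character(0))
    coh <- generate_cohort(cfg, seed = 13)
    sp <- vapply(coh$profiles, function(p) p$styles$normal$turn_speed_ms,
                 numeric(1))
    abs(mean(sp[coh$roster$status == "Healthy"]) -
        mean(sp[coh$roster$status == "MCI"]))
  }, numeric(1))
  expect_true(all(diff(gap) >= 0))
})

test_that("subject profiles enforce positivity and effect invariants", {
  expect_error(subject_profile("a", "Healthy", speed_mult = 0), "positive")
  expect_error(subject_profile("a", "Healthy", effect_size = -1), ">= 0")
  # effect_size = 0: MCI and healthy profiles share identical style params
  ph <- subject_profile("a", "Healthy", effect_size = 0)
  pm <- subject_profile("a", "MCI", effect_size = 0)
  expect_identical(ph$styles, pm$styles)
})
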