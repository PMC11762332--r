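test_that("angular acceleration extrema match exhaustive finite differences", {
  t <- seq(0, 1, by = 0.1)
  expect_equal(compute_angular_acceleration(rep(0.4, 11), t),
               c(alpha_max = 0, alpha_min = 0))
  expect_equal(compute_angular_acceleration(0.5 * t, t),
               c(alpha_max = 0.5, alpha_min = 0.5))
  # triangular: rise 1 rad/s over 1 s, fall symmetrically
  tt <- seq(0, 2, by = 0.1)
  tri <- c(seq(0, 1, by = 0.1), seq(0.9, 0, by = -0.1))
  expect_equal(compute_angular_acceleration(tri, tt),
               c(alpha_max = 1, alpha_min = -1))
  # random windows: exact agreement with a brute-force loop
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:40, 1)
    w <- rnorm(n)
    tw <- seq(0, by = 0.1, length.out = n)
    got <- compute_angular_acceleration(w, tw)
    alphas <- numeric(n - 1)
    for (i in seq_len(n - 1)) alphas[i] <- (w[i + 1] - w[i]) / (tw[i + 1] - tw[i])
    expect_identical(got, c(alpha_max = max(alphas), alpha_min = min(alphas)))
  }
  expect_error(compute_angular_acceleration(1, 0), "at least 2")
})

test_that("peak detection finds isolated lobes and ignores quiet traces", {
  t <- seq(0, 30, by = 0.1)
  expect_length(detect_turn_peaks(make_trace(t, rep(0, length(t)))), 0)

  # single Gaussian lobe, amplitude 0.6 rad/s, width 2 s
  gz <- 0.6 * exp(-(t - 10)^2 / (2 * 2^2))
  w <- detect_turn_peaks(make_trace(t, gz),
                         detection_params(threshold = 0.2))
  expect_length(w, 1)
  expect_lte(abs(w[[1]]$peak_idx - which.max(gz)), 1)  # brute-force argmax
  expect_lte(w[[1]]$start_idx, w[[1]]$peak_idx)
  expect_lte(w[[1]]$peak_idx, w[[1]]$end_idx)

  # two opposite lobes 10 s apart give two windows with opposite peak signs
  gz2 <- 0.6 * exp(-(t - 8)^2 / 2) - 0.7 * exp(-(t - 18)^2 / 2)
  w2 <- detect_turn_peaks(make_trace(t, gz2),
                          detection_params(threshold = 0.2))
  expect_length(w2, 2)
  expect_gt(gz2[w2[[1]]$peak_idx], 0)
  expect_lt(gz2[w2[[2]]$peak_idx], 0)
  expect_lte(abs(w2[[1]]$peak_idx - which.max(gz2)), 1)
  expect_lte(abs(w2[[2]]$peak_idx - which.min(gz2)), 1)
  # non-overlapping windows
  expect_lt(w2[[1]]$end_idx, w2[[2]]$start_idx)
})

test_that("each detected window holds exactly one suprathreshold excursion peak", {
  set.seed(31)
  t <- seq(0, 120, by = 0.1)
  centers <- c(15, 40, 65, 90, 110)
  amps <- c(0.5, -0.6, 0.45, 0.7, -0.4)
  gz <- rowSums(vapply(seq_along(centers), function(i) {
    amps[i] * exp(-(t - centers[i])^2 / (2 * 1.5^2))
  }, numeric(length(t)))) + rnorm(length(t), 0, 0.01)
  ws <- detect_turn_peaks(make_trace(t, gz), detection_params(threshold = 0.2))
  expect_length(ws, 5)
  for (w in ws) {
    idx <- w$start_idx:w$end_idx
    expect_equal(w$peak_idx, idx[which.max(abs(gz[idx]))])
  }
  starts <- vapply(ws, `[[`, 0L, "start_idx")
  ends <- vapply(ws, `[[`, 0L, "end_idx")
  expect_true(all(starts[-1] > ends[-length(ends)]))
})

test_that("turn classification follows the 45/135 degree angle cuts", {
  params <- detection_params()
  const_window <- function(angle, dur = 2) {
    n <- as.integer(dur / 0.1) + 1
    t <- seq(0, dur, by = 0.1)
    trace <- make_trace(t, rep(angle / dur, n))
    list(trace = trace,
         window = structure(list(start_idx = 1L, peak_idx = (n + 1L) %/% 2L,
                                 end_idx = n), class = "turn_window"))
  }
  cw <- const_window(pi / 2)
  expect_equal(classify_turn(cw$window, cw$trace, params)$turn_type, "left90")
  cw <- const_window(-pi)
  expect_equal(classify_turn(cw$window, cw$trace, params)$turn_type, "uturn")
  cw <- const_window(0.3)
  expect_equal(classify_turn(cw$window, cw$trace, params)$turn_type, "minor")
  cw <- const_window(-pi / 2)
  expect_equal(classify_turn(cw$window, cw$trace, params)$turn_type, "right90")
  # inverted mounting flips left and right
  flipped <- detection_params(left_positive = FALSE)
  cw <- const_window(pi / 2)
  expect_equal(classify_turn(cw$window, cw$trace, flipped)$turn_type, "right90")
})

test_that("minor turns and events nested in U-turn windows are excluded", {
  ev <- data.frame(
    turn_type = c("uturn", "minor", "left90", "right90"),
    condition = "normal",
    peak_omega = c(0.6, 0.1, 0.4, -0.4),
    alpha_max = 0.2, alpha_min = -0.2, mean_speed = 4,
    duration = c(8, 1, 5, 5), integrated_angle = c(pi, 0.2, pi / 2, -pi / 2),
    start_idx = 1L, peak_idx = 1L, end_idx = 1L,
    start_t = c(0, 2, 20, 40), end_t = c(10, 3, 25, 45),
    stringsAsFactors = FALSE
  )
  out <- exclude_minor_turns(ev)
  expect_equal(out$turn_type, c("uturn", "left90", "right90"))

  # a non-minor event nested inside a U-turn window is also dropped
  ev2 <- ev
  ev2$turn_type[2] <- "left90"
  out2 <- exclude_minor_turns(ev2)
  expect_equal(out2$turn_type, c("uturn", "left90", "right90"))
  expect_equal(out2$start_t, c(0, 20, 40))

  expect_equal(exclude_minor_turns(ev[ev$turn_type != "minor", ]),
               ev[ev$turn_type != "minor", ])
  expect_equal(nrow(exclude_minor_turns(ev[ev$turn_type == "minor", ])), 0)
})

test_that("turn speed is the window mean of synchronized speed", {
  t <- seq(0, 1, by = 0.1)
  w <- structure(list(start_idx = 1L, peak_idx = 6L, end_idx = 11L),
                 class = "turn_window")
  expect_equal(turn_speed(w, make_trace(t, rep(0, 11), rep(10, 11))), 10)
  expect_equal(turn_speed(w, make_trace(t, rep(0, 11), seq(0, 10, length.out = 11))), 5)
  w1 <- structure(list(start_idx = 3L, peak_idx = 3L, end_idx = 3L),
                  class = "turn_window")
  expect_equal(turn_speed(w1, make_trace(t, rep(0, 11), seq(0, 10, length.out = 11))), 2)
})

test_that("zero-noise sessions recover designed turn counts for every lap", {
  p <- zero_noise_profile()
  s <- simulate_session(p, build_circuit(), "normal", seed = 1)
  ev <- exclude_minor_turns(detect_turn_events(s))
  tab <- table(factor(ev$turn_type, levels = c("left90", "right90", "uturn")))
  expect_equal(as.integer(tab), c(20L, 20L, 20L))
  # 6 designed turns in each of the 10 laps (zero jitter: laps are equal-length
  # sample blocks, so lap boundaries fall at equal index intervals)
  lap_of <- floor((ev$peak_idx - 1) / (nrow(s$imu) / 10))
  expect_equal(as.integer(table(factor(lap_of, levels = 0:9))), rep(6L, 10))
})

test_that("kinematic parameters are recovered within 2% (zero noise) and 10% (default noise)", {
  p0 <- zero_noise_profile()
  circ <- build_circuit()
  for (cond in c("normal", "aggressive")) {
    s <- simulate_session(p0, circ, cond, seed = 5)
    ev <- exclude_minor_turns(detect_turn_events(s))
    for (ty in c("left90", "right90", "uturn")) {
      got_p <- mean(abs(ev$peak_omega[ev$turn_type == ty]))
      want_p <- mean(s$truth$peak_yaw[s$truth$kind == ty])
      expect_lt(abs(got_p - want_p) / want_p, 0.02)
      got_s <- mean(ev$mean_speed[ev$turn_type == ty])
      want_s <- mean(s$truth$turn_speed[s$truth$kind == ty])
      expect_lt(abs(got_s - want_s) / want_s, 0.02)
    }
  }
  pn <- subject_profile("noisy", "Healthy")
  s <- simulate_session(pn, circ, "normal", seed = 5)
  ev <- exclude_minor_turns(detect_turn_events(s))
  for (ty in c("left90", "right90", "uturn")) {
    got_p <- mean(abs(ev$peak_omega[ev$turn_type == ty]))
    want_p <- mean(s$truth$peak_yaw[s$truth$kind == ty])
    expect_lt(abs(got_p - want_p) / want_p, 0.10)
    got_s <- mean(ev$mean_speed[ev$turn_type == ty])
    want_s <- mean(s$truth$turn_speed[s$truth$kind == ty])
    expect_lt(abs(got_s - want_s) / want_s, 0.10)
  }
})

test_that("scaling yaw rate scales angular-velocity features and leaves speed alone", {
  p <- zero_noise_profile()
  s <- simulate_session(p, build_circuit(laps = 2), "normal", seed = 8)
  s_scaled <- s
  s_scaled$imu$gz <- 1.2 * s$imu$gz
  f1 <- extract_features(list(s))
  f2 <- extract_features(list(s_scaled))
  vel <- grepl("yawvel", names(f1))
  spd <- grepl("speed", names(f1))
  ok <- !attr(f1, "missing") & !attr(f2, "missing")
  expect_equal(unclass(f2)[vel & ok], 1.2 * unclass(f1)[vel & ok],
               tolerance = 1e-8)
  expect_equal(unclass(f2)[spd & ok], unclass(f1)[spd & ok], tolerance = 1e-8)
})
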