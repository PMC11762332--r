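test_that("sensor logs round-trip bit-stably at the printed precision", {
  p <- subject_profile("rt", "Healthy")
  s <- simulate_session(p, build_circuit(laps = 1), "normal", seed = 2)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a_imu.csv"); g1 <- file.path(d, "a_gps.csv")
  write_sensor_log(s, f1, g1)
  r <- read_sensor_log(f1, g1, subject_id = "rt", condition = "normal")
  # write the re-read session again: bytes must be identical
  f2 <- file.path(d, "b_imu.csv"); g2 <- file.path(d, "b_gps.csv")
  write_sensor_log(r, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(r$imu$gz, s$imu$gz, tolerance = 1e-8)
  expect_equal(r$gps$speed, s$gps$speed, tolerance = 1e-8)
})

test_that("malformed sensor logs are rejected with informative messages", {
  p <- subject_profile("bad", "Healthy")
  s <- simulate_session(p, build_circuit(laps = 1), "normal", seed = 2)
  d <- withr::local_tempdir()
  f <- file.path(d, "imu.csv"); g <- file.path(d, "gps.csv")
  write_sensor_log(s, f, g)

  # shuffled timestamps
  imu <- utils::read.csv(f)
  set.seed(1)
  shuf <- imu[sample(nrow(imu)), ]
  fs <- file.path(d, "shuffled.csv")
  utils::write.csv(shuf, fs, row.names = FALSE)
  expect_error(read_sensor_log(fs, g), "strictly increasing")

  # missing gz column, named in the message
  fm <- file.path(d, "nogz.csv")
  utils::write.csv(imu[, setdiff(names(imu), "gz")], fm, row.names = FALSE)
  expect_error(read_sensor_log(fm, g), "gz")

  # empty channel
  fe <- file.path(d, "empty.csv")
  utils::write.csv(imu[0, ], fe, row.names = FALSE)
  expect_error(read_sensor_log(fe, g), "empty")

  expect_error(read_sensor_log(file.path(d, "nope.csv"), g), "not found")
})

test_that("GPS synchronization equals the two-point linear interpolation oracle", {
  set.seed(4)
  for (rep in 1:5) {
    n_gps <- sample(5:15, 1)
    t_gps <- sort(runif(n_gps, 0, 30))
    sp <- runif(n_gps, 0, 15)
    t_imu <- sort(runif(80, min(t_gps), max(t_gps)))
    sess <- make_session(
      imu = data.frame(t = t_imu, ax = 0, ay = 0, az = 0, gx = 0, gy = 0,
                       gz = rnorm(80)),
      gps = data.frame(t = t_gps, lat = 0, lon = 0, speed = sp)
    )
    got <- synchronize_gps(sess)$speed
    # brute-force two-point interpolation
    want <- vapply(t_imu, function(tt) {
      i <- max(which(t_gps <= tt))
      if (i == n_gps) return(sp[n_gps])
      sp[i] + (sp[i + 1] - sp[i]) * (tt - t_gps[i]) / (t_gps[i + 1] - t_gps[i])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("synchronization handles knots, constants, edges and degenerate input", {
  sess <- make_session(
    imu = data.frame(t = c(0, 0.5, 1), ax = 0, ay = 0, az = 0,
                     gx = 0, gy = 0, gz = 0),
    gps = data.frame(t = c(0, 1), lat = 0, lon = 0, speed = c(0, 10))
  )
  tr <- synchronize_gps(sess)
  expect_equal(tr$speed, c(0, 5, 10))          # midpoint and both knots

  sess$gps$speed <- c(10, 10)
  expect_equal(synchronize_gps(sess)$speed, c(10, 10, 10))

  # imu timestamps outside the GPS span clamp to the nearest edge value
  sess2 <- make_session(
    imu = data.frame(t = c(-1, 0.5, 3), ax = 0, ay = 0, az = 0,
                     gx = 0, gy = 0, gz = 0),
    gps = data.frame(t = c(0, 1), lat = 0, lon = 0, speed = c(2, 4))
  )
  expect_equal(synchronize_gps(sess2)$speed, c(2, 3, 4))

  sess3 <- make_session(
    imu = data.frame(t = 0, ax = 0, ay = 0, az = 0, gx = 0, gy = 0, gz = 0),
    gps = data.frame(t = 0, lat = 0, lon = 0, speed = 1)
  )
  expect_error(synchronize_gps(sess3), "at least 2 GPS")
})

test_that("roster and cohort I/O round-trip", {
  d <- withr::local_tempdir()
  r <- default_roster()
  expect_equal(nrow(r), 21)
  p <- file.path(d, "roster.csv")
  write_roster(r, p)
  expect_identical(read_roster(p), r)

  bad <- r; bad$status[1] <- "Unknown"
  pb <- file.path(d, "bad.csv")
  write_roster(bad, pb)
  expect_error(read_roster(pb), "Unknown")

  cfg <- cohort_config(circuit = build_circuit(laps = 1),
                       n_healthy = 2, n_mci = 2)
  coh <- generate_cohort(cfg, seed = 6)
  write_cohort(coh, file.path(d, "cohort"))
  back <- read_cohort(file.path(d, "cohort"))
  expect_equal(back$roster, coh$roster)
  expect_length(back$sessions, 8)
  expect_equal(back$sessions[[1]]$imu$gz, coh$sessions[[1]]$imu$gz,
               tolerance = 1e-8)
})
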