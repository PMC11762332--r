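#' Simulate one sensor session
#'
#' Generates the multirate sensor record of one subject driving the circuit
#' for `circuit$laps` laps under one condition: IMU samples (accelerometer +
#' gyroscope) at 10 Hz and GPS (position + speed) at 1 Hz.
#'
#' The yaw-rate trace is built per turn segment as a trapezoidal lobe: ramp at
#' the profile's yaw-ramp rate up to the peak yaw-rate, plateau, ramp down
#' (degenerating to a triangle when the turn angle is too small for a
#' plateau). Each lobe's sampled integral is calibrated to the segment's
#' designed heading change exactly, so cumulative heading advances by exactly
#' \eqn{2\pi} per lap at zero noise. Speed is constant within a segment; the
#' final straight of every lap absorbs the distance residual so that the
#' travelled path length of each lap equals `circuit$lap_length_m` exactly.
#' GPS positions are produced by dead-reckoning integration of the planar
#' trajectory, expressed as WGS-84 degrees around `origin`.
#'
#' @param profile a [subject_profile()].
#' @param circuit a [build_circuit()] result.
#' @param condition `"normal"` or `"aggressive"`.
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   sessions.
#' @param imu_hz,gps_hz nominal sampling rates.
#' @param origin latitude/longitude (degrees) of the trajectory origin.
#' @return object of class `sensor_session`: list with `subject_id`,
#'   `condition`, `imu` (data frame `t, ax, ay, az, gx, gy, gz`), `gps`
#'   (data frame `t, lat, lon, speed`) and `truth` (per-turn design table,
#'   present only for simulated sessions).
#' @examples
#' p <- subject_profile("demo", "Healthy")
#' s <- simulate_session(p, build_circuit(laps = 1), "normal", seed = 1)
#' s
#' @export
simulate_session <- function(profile, circuit, condition = c("normal", "aggressive"),
                             seed = 1L, imu_hz = 10, gps_hz = 1,
                             origin = c(lat = 33.435, lon = -111.943)) {
  condition <- match.arg(condition)
  stopifnot(inherits(profile, "subject_profile"),
            inherits(circuit, "circuit_spec"))
  seed <- as.integer(seed)
  style <- profile$styles[[condition]]
  noise <- profile$noise
  dt <- 1 / imu_hz

  set.seed(seed)

  seg <- circuit$segments
  turn_rows <- which(seg$kind != "straight")
  straight_rows <- which(seg$kind == "straight")
  n_straight <- length(straight_rows)

  omega_all <- list()
  speed_all <- list()
  truth <- list()

  for (lap in seq_len(circuit$laps)) {
    # draw per-turn jitter for this lap, then lay out segments in order
    jit_v <- pmax(1 + stats::rnorm(length(turn_rows), 0, style$turn_jitter_cv), 0.2)
    jit_y <- pmax(1 + stats::rnorm(length(turn_rows), 0, style$turn_jitter_cv), 0.2)

    turn_pieces <- vector("list", nrow(seg))
    turn_dist <- 0
    ti <- 0L
    for (i in turn_rows) {
      ti <- ti + 1L
      theta <- abs(seg$angle_rad[i])
      sgn <- sign(seg$angle_rad[i])
      A <- switch(seg$kind[i],
                  left90 = style$peak_yaw_90, right90 = style$peak_yaw_90,
                  uturn = style$peak_yaw_uturn) * jit_y[ti]
      rho <- style$yaw_ramp * jit_y[ti]
      v <- style$turn_speed_ms * jit_v[ti]

      if (A^2 / rho >= theta) {      # no room for a plateau: triangular lobe
        A <- sqrt(theta * rho)
        t_ramp <- A / rho
        t_plat <- 0
      } else {
        t_ramp <- A / rho
        t_plat <- (theta - A^2 / rho) / A
      }
      T_lobe <- 2 * t_ramp + t_plat
      n <- max(4L, as.integer(round(T_lobe / dt)))
      tau <- (seq_len(n) - 0.5) * (T_lobe / n)   # midpoint samples of the lobe
      w <- ifelse(tau < t_ramp, rho * tau,
                  ifelse(tau < t_ramp + t_plat, A, rho * (T_lobe - tau)))
      w <- pmax(w, 0)
      # calibrate the sampled integral to the designed heading change
      w <- w * (theta / (sum(w) * dt)) * sgn
      turn_pieces[[i]] <- list(omega = w, speed = rep(v, n))
      turn_dist <- turn_dist + v * n * dt
      truth[[length(truth) + 1L]] <- data.frame(
        lap = lap, segment = i, kind = seg$kind[i],
        peak_yaw = max(abs(w)), turn_speed = v, yaw_ramp = rho,
        duration = n * dt, angle_rad = seg$angle_rad[i]
      )
    }

    budget <- circuit$lap_length_m - turn_dist
    if (budget <= 0)
      stopf(paste0("turn maneuvers cover %.1f m at these speeds, exceeding the ",
                   "%.0f m lap; shorten turns or raise the lap length"),
            turn_dist, circuit$lap_length_m)
    v_s <- style$straight_speed_ms
    share <- budget / n_straight
    # straights use a trapezoidal motion profile: brake to the next turn's
    # speed before the turn, accelerate back to cruise after it
    if (!exists("prev_speed", inherits = FALSE)) prev_speed <- v_s
    for (i in seq_len(nrow(seg))) {
      if (seg$kind[i] == "straight") {
        nxt <- turn_rows[turn_rows > i]
        v_out <- if (length(nxt) > 0) turn_pieces[[nxt[1]]]$speed[1] else v_s
        v <- straight_profile(share, prev_speed, v_out, v_s,
                              style$accel_ms2, dt)
        turn_pieces[[i]] <- list(omega = rep(0, length(v)), speed = v)
      }
      prev_speed <- turn_pieces[[i]]$speed[length(turn_pieces[[i]]$speed)]
    }
    omega_all[[lap]] <- unlist(lapply(turn_pieces, `[[`, "omega"))
    speed_all[[lap]] <- unlist(lapply(turn_pieces, `[[`, "speed"))
  }

  omega <- unlist(omega_all)
  speed <- unlist(speed_all)
  N <- length(omega)
  t_imu <- (seq_len(N) - 1L) * dt

  heading <- cumsum(omega) * dt
  h_prev <- c(0, heading[-N])
  step <- speed * dt
  # N+1 positions starting at the origin: the sum of consecutive Euclidean
  # distances equals the integrated travelled distance exactly
  x <- c(0, cumsum(step * cos(h_prev)))
  y <- c(0, cumsum(step * sin(h_prev)))

  ax_clean <- c(0, diff(speed)) / dt
  ay_clean <- speed * omega

  imu <- data.frame(
    t = t_imu,
    ax = ax_clean + stats::rnorm(N, 0, noise$accel_sd),
    ay = ay_clean + stats::rnorm(N, 0, noise$accel_sd),
    az = 9.81 + stats::rnorm(N, 0, noise$accel_sd),
    gx = stats::rnorm(N, 0, noise$gyro_sd),
    gy = stats::rnorm(N, 0, noise$gyro_sd),
    gz = omega + stats::rnorm(N, 0, noise$gyro_sd)
  )

  t_pos <- (0:N) * dt
  t_gps <- seq(0, ceiling(t_imu[N]), by = 1 / gps_hz)
  sp_gps <- stats::approx(t_imu, speed, xout = t_gps, rule = 2)$y +
    stats::rnorm(length(t_gps), 0, noise$gps_speed_sd)
  x_gps <- stats::approx(t_pos, x, xout = t_gps, rule = 2)$y
  y_gps <- stats::approx(t_pos, y, xout = t_gps, rule = 2)$y
  m_per_deg_lat <- 111320
  gps <- data.frame(
    t = t_gps,
    lat = origin[["lat"]] + y_gps / m_per_deg_lat,
    lon = origin[["lon"]] + x_gps / (m_per_deg_lat * cos(origin[["lat"]] * pi / 180)),
    speed = sp_gps
  )

  structure(
    list(subject_id = profile$subject_id, condition = condition,
         imu = imu, gps = gps,
         truth = do.call(rbind, truth),
         trajectory = data.frame(t = t_pos, x = x, y = y),
         seed = seed),
    class = "sensor_session"
  )
}

# Trapezoidal speed profile for one straight segment: accelerate from v_in
# toward the cruise speed, cruise, brake to v_out, covering distance d
# exactly (the sampled profile is rescaled to calibrate the discrete sum).
# If d is too short even for a direct ramp, the ramp is steepened to fit.
straight_profile <- function(d, v_in, v_out, v_max, a, dt) {
  stopifnot(d > 0, v_in > 0, v_out > 0, v_max > 0, a > 0)
  d_min <- abs(v_in^2 - v_out^2) / (2 * a)
  if (d_min > d) a <- abs(v_in^2 - v_out^2) / (2 * d)
  v_p <- min(v_max, sqrt((2 * a * d + v_in^2 + v_out^2) / 2))
  v_p <- max(v_p, v_in, v_out)
  t_acc <- (v_p - v_in) / a
  t_dec <- (v_p - v_out) / a
  d_cruise <- d - (v_p^2 - v_in^2) / (2 * a) - (v_p^2 - v_out^2) / (2 * a)
  t_cr <- max(d_cruise, 0) / v_p
  T_all <- t_acc + t_cr + t_dec
  n <- max(1L, as.integer(round(T_all / dt)))
  tau <- (seq_len(n) - 0.5) * (T_all / n)
  v <- ifelse(tau < t_acc, v_in + a * tau,
              ifelse(tau < t_acc + t_cr, v_p, v_out + a * (T_all - tau)))
  v * (d / (sum(v) * dt))
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf("<sensor_session> subject %s, %s condition\n",
              x$subject_id, x$condition))
  cat(sprintf("  imu: %d samples @ %.1f Hz | gps: %d samples @ %.1f Hz | %.0f s\n",
              nrow(x$imu), 1 / stats::median(diff(x$imu$t)),
              nrow(x$gps), 1 / stats::median(diff(x$gps$t)),
              max(x$imu$t)))
  invisible(x)
}

#' Cumulative heading of a session
#'
#' Integrates the yaw-rate channel over time. At zero noise the heading
#' advances by exactly \eqn{2\pi} per completed circuit lap, so
#' `floor(max(cumulative_heading(s)) / (2*pi))` counts completed laps.
#'
#' @param session a `sensor_session`.
#' @return numeric vector, cumulative heading in radians at each IMU sample.
#' @export
cumulative_heading <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  dt <- c(diff(session$imu$t), stats::median(diff(session$imu$t)))
  cumsum(session$imu$gz * dt)
}

#' Count completed heading cycles
#'
#' @param session a `sensor_session`.
#' @return integer: completed multiples of \eqn{2\pi} in cumulative heading
#'   (small numerical slack of 1e-6 rad).
#' @export
count_laps <- function(session) {
  h <- cumulative_heading(session)
  as.integer(floor(max(abs(h)) / (2 * pi) + 1e-6))
}

#' Travelled path length of a session trajectory
#'
#' Sums Euclidean distances between consecutive planar trajectory samples.
#' For a simulated session this is the integrated path length over all laps.
#'
#' @param session a `sensor_session` carrying a `trajectory` element.
#' @return length in meters.
#' @export
path_length <- function(session) {
  stopifnot(inherits(session, "sensor_session"),
            !is.null(session$trajectory))
  tr <- session$trajectory
  sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
}

#' Generate a simulated cohort
#'
#' Draws one [subject_profile()] per roster row (subject-level speed/yaw
#' multipliers around 1 with CV `between_subject_cv`, plus the MCI status
#' effect) and simulates one session per requested condition. All child seeds
#' derive deterministically from `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @return object of class `drive_cohort`: list with `roster` (data frame),
#'   `sessions` (named list of `sensor_session`, names
#'   `"<subject_id>.<condition>"`), and `profiles`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(circuit = build_circuit(laps = 2)))
#' nrow(coh$roster)      # 21
#' length(coh$sessions)  # 42
#' }
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- as.integer(seed)

  roster <- if (is.null(config$n_healthy) && is.null(config$n_mci)) {
    default_roster()
  } else {
    synthetic_roster(config$n_healthy %||% 0, config$n_mci %||% 0,
                     seed = child_seed(seed, "roster"))
  }

  profiles <- list()
  sessions <- list()
  for (i in seq_len(nrow(roster))) {
    sid <- roster$subject_id[i]
    set.seed(child_seed(seed, sid, "profile"))
    mults <- pmax(1 + stats::rnorm(2, 0, config$between_subject_cv), 0.3)
    prof <- subject_profile(
      subject_id = sid, status = roster$status[i],
      age = roster$age[i], sex = roster$sex[i],
      base_styles = config$styles, noise = config$noise,
      effect = config$effect, effect_size = config$effect_size,
      speed_mult = mults[1], yaw_mult = mults[2]
    )
    profiles[[sid]] <- prof
    for (cond in config$conditions) {
      sessions[[paste(sid, cond, sep = ".")]] <-
        simulate_session(prof, config$circuit, cond,
                         seed = child_seed(seed, sid, cond))
    }
  }

  structure(list(roster = roster, sessions = sessions, profiles = profiles,
                 config = config, seed = seed),
            class = "drive_cohort")
}

#' @export
print.drive_cohort <- function(x, ...) {
  cat(sprintf("<drive_cohort> %d subjects (%d Healthy, %d MCI), %d sessions\n",
              nrow(x$roster), sum(x$roster$status == "Healthy"),
              sum(x$roster$status == "MCI"), length(x$sessions)))
  invisible(x)
}
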