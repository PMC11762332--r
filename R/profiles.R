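#' Default driving-style parameters
#'
#' Kinematic parameters of the two protocol conditions. Normal driving uses
#' smooth, controlled turns; aggressive driving uses sharper turns at higher
#' speed (peak yaw-rates scaled 1.6x and steeper yaw ramps).
#'
#' @param normal,aggressive named lists overriding individual parameters:
#'   `turn_speed_ms` (m/s, speed held through turns), `straight_speed_ms`
#'   (m/s, cruise speed on straights), `peak_yaw_90` and `peak_yaw_uturn`
#'   (rad/s, peak yaw-rate in 90-degree and U-turns), `yaw_ramp` (rad/s^2,
#'   ramp rate of the yaw-rate lobe), `accel_ms2` (m/s^2, longitudinal
#'   acceleration/braking rate between cruise and turn speed),
#'   `turn_jitter_cv` (lap-to-lap coefficient of variation of per-turn speed
#'   and peak yaw-rate).
#' @return named list with elements `normal` and `aggressive`.
#' @export
driving_styles <- function(normal = list(), aggressive = list()) {
  base_normal <- list(turn_speed_ms = 4, straight_speed_ms = 8,
                      peak_yaw_90 = 0.4, peak_yaw_uturn = 0.6,
                      yaw_ramp = 0.2, accel_ms2 = 0.8, turn_jitter_cv = 0.05)
  base_aggr <- list(turn_speed_ms = 7, straight_speed_ms = 11,
                    peak_yaw_90 = 0.4 * 1.6, peak_yaw_uturn = 0.6 * 1.6,
                    yaw_ramp = 0.5, accel_ms2 = 1.5, turn_jitter_cv = 0.05)
  list(normal = utils::modifyList(base_normal, normal),
       aggressive = utils::modifyList(base_aggr, aggressive))
}

#' Sensor noise parameters
#'
#' Additive Gaussian noise standard deviations per channel.
#'
#' @param gyro_sd rad/s, gyroscope channels.
#' @param accel_sd m/s^2, accelerometer channels.
#' @param gps_speed_sd m/s, GPS speed.
#' @return named list of standard deviations.
#' @export
noise_params <- function(gyro_sd = 0.02, accel_sd = 0.05, gps_speed_sd = 0.2) {
  stopifnot(gyro_sd >= 0, accel_sd >= 0, gps_speed_sd >= 0)
  list(gyro_sd = gyro_sd, accel_sd = accel_sd, gps_speed_sd = gps_speed_sd)
}

#' MCI status-effect parameters
#'
#' The cognitive-status effect is modeled as a multiplicative shift on turn
#' kinematics plus inflated within-subject variability. At `effect_size = s`,
#' an MCI subject's turn speed and peak yaw-rate are multiplied by
#' `1 - speed_shift*s` and `1 - yaw_shift*s`, and the lap-to-lap jitter CV by
#' `1 + variability*s`. `effect_size = 0` makes the status-conditional
#' distributions identical. The default magnitudes are simulator parameters,
#' not empirical claims.
#'
#' @param speed_shift,yaw_shift fractional reductions per unit effect size.
#' @param variability fractional inflation of within-subject variability per
#'   unit effect size.
#' @return named list of effect parameters.
#' @export
effect_params <- function(speed_shift = 0.15, yaw_shift = 0.15,
                          variability = 0.30) {
  list(speed_shift = speed_shift, yaw_shift = yaw_shift,
       variability = variability)
}

#' Construct a subject profile
#'
#' A subject profile carries the per-condition driving-style parameters a
#' simulated subject uses, after applying (a) subject-level multipliers
#' (between-subject variability) and (b) the MCI status effect.
#'
#' @param subject_id character or integer identifier.
#' @param status `"Healthy"` or `"MCI"`.
#' @param age,sex roster demographics (not used by the kinematics).
#' @param base_styles output of [driving_styles()].
#' @param noise output of [noise_params()].
#' @param effect output of [effect_params()].
#' @param effect_size dimensionless multiplier on the MCI effect; 0 disables
#'   it.
#' @param speed_mult,yaw_mult subject-level multipliers on speed and yaw-rate
#'   parameters (default 1; [generate_cohort()] draws them around 1).
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, status = c("Healthy", "MCI"),
                            age = 75, sex = "Female",
                            base_styles = driving_styles(),
                            noise = noise_params(),
                            effect = effect_params(),
                            effect_size = 1,
                            speed_mult = 1, yaw_mult = 1) {
  status <- match.arg(status)
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (speed_mult <= 0 || yaw_mult <= 0)
    stopf("subject multipliers must be strictly positive")

  is_mci <- status == "MCI"
  m_speed <- speed_mult * if (is_mci) max(1 - effect$speed_shift * effect_size, 0.05) else 1
  m_yaw <- yaw_mult * if (is_mci) max(1 - effect$yaw_shift * effect_size, 0.05) else 1
  m_jit <- if (is_mci) 1 + effect$variability * effect_size else 1

  styles <- lapply(base_styles, function(s) {
    out <- list(
      turn_speed_ms = s$turn_speed_ms * m_speed,
      straight_speed_ms = s$straight_speed_ms * m_speed,
      peak_yaw_90 = s$peak_yaw_90 * m_yaw,
      peak_yaw_uturn = s$peak_yaw_uturn * m_yaw,
      yaw_ramp = s$yaw_ramp * m_yaw,
      accel_ms2 = s$accel_ms2,
      turn_jitter_cv = s$turn_jitter_cv * m_jit
    )
    if (any(unlist(out[1:6]) <= 0)) stopf("speeds and rates must be positive")
    out
  })

  structure(
    list(subject_id = as.character(subject_id), age = age, sex = sex,
         status = status, styles = styles, noise = noise,
         effect_size = effect_size),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s (%s, %s, age %s)\n",
              x$subject_id, x$status, x$sex, x$age))
  n <- x$styles$normal
  cat(sprintf("  normal: turn %.2f m/s, peak yaw %.3f/%.3f rad/s\n",
              n$turn_speed_ms, n$peak_yaw_90, n$peak_yaw_uturn))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' Bundles everything [generate_cohort()] needs. With `n_healthy` and `n_mci`
#' both `NULL`, the packaged 21-subject reference roster (13 healthy, 8 MCI)
#' is used; otherwise a synthetic roster with the requested counts is built.
#'
#' @param circuit a [build_circuit()] result.
#' @param styles [driving_styles()] result.
#' @param noise [noise_params()] result.
#' @param effect [effect_params()] result.
#' @param effect_size dimensionless MCI effect multiplier.
#' @param n_healthy,n_mci subject counts, or `NULL` for the reference roster.
#' @param between_subject_cv coefficient of variation of the subject-level
#'   speed and yaw multipliers.
#' @param conditions which protocol conditions to simulate per subject.
#' @param seed default master seed used when [generate_cohort()] is called
#'   without one.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(circuit = build_circuit(),
                          styles = driving_styles(),
                          noise = noise_params(),
                          effect = effect_params(),
                          effect_size = 1,
                          n_healthy = NULL, n_mci = NULL,
                          between_subject_cv = 0.10,
                          conditions = c("normal", "aggressive"),
                          seed = 1L) {
  stopifnot(inherits(circuit, "circuit_spec"))
  if (!all(conditions %in% c("normal", "aggressive")))
    stopf("conditions must be a subset of {normal, aggressive}")
  structure(
    list(circuit = circuit, styles = styles, noise = noise, effect = effect,
         effect_size = effect_size, n_healthy = n_healthy, n_mci = n_mci,
         between_subject_cv = between_subject_cv, conditions = conditions,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' The packaged reference roster
#'
#' The 21-subject cohort roster (ID, age, sex, cognitive status; 13 healthy,
#' 8 MCI) shipped with the package and used as the default simulated cohort.
#'
#' @return data frame with columns `subject_id`, `age`, `sex`, `status`.
#' @export
default_roster <- function() {
  path <- system.file("extdata", "cohort_roster.csv", package = "drivecog",
                      mustWork = TRUE)
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  r$subject_id <- as.character(r$subject_id)
  r
}

# synthesize a roster with given status counts (ages/sex are cosmetic)
synthetic_roster <- function(n_healthy, n_mci, seed) {
  n <- n_healthy + n_mci
  if (n == 0)
    return(data.frame(subject_id = character(0), age = integer(0),
                      sex = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  set.seed(seed)
  data.frame(
    subject_id = sprintf("SY%02d", seq_len(n)),
    age = sample(65:85, n, replace = TRUE),
    sex = rep_len(c("Male", "Female"), n),
    status = c(rep("Healthy", n_healthy), rep("MCI", n_mci)),
    stringsAsFactors = FALSE
  )
}
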