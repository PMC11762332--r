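#' Write a sensor session to CSV logs
#'
#' Serializes a session as two CSV files: an IMU log with columns
#' `t,ax,ay,az,gx,gy,gz` (s, m/s^2, rad/s) and a GPS log with columns
#' `t,lat,lon,speed` (s, degrees, m/s). Timestamps are seconds from session
#' start. Values are printed with 9 significant digits, enough for bit-stable
#' round trips at sensor noise scales.
#'
#' @param session a `sensor_session`.
#' @param imu_path,gps_path output file paths.
#' @return invisibly, a named character vector of the two paths.
#' @seealso [read_sensor_log()]
#' @export
write_sensor_log <- function(session, imu_path, gps_path) {
  stopifnot(inherits(session, "sensor_session"))
  fmt <- function(df) {
    out <- df
    for (j in seq_along(out)) out[[j]] <- formatC(out[[j]], digits = 9, format = "g")
    out
  }
  utils::write.csv(fmt(session$imu), imu_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(session$gps), gps_path, row.names = FALSE, quote = FALSE)
  invisible(c(imu = imu_path, gps = gps_path))
}

#' Read a sensor session from CSV logs
#'
#' Inverse of [write_sensor_log()]. Validates the schema (required columns,
#' nonempty channels, strictly increasing timestamps) and fails with the
#' offending column or row in the message.
#'
#' @param imu_path,gps_path paths written by [write_sensor_log()].
#' @param subject_id,condition metadata to attach (not stored in the logs).
#' @return a `sensor_session` (without simulation ground truth).
#' @export
read_sensor_log <- function(imu_path, gps_path,
                            subject_id = NA_character_,
                            condition = NA_character_) {
  imu <- read_channel(imu_path, c("t", "ax", "ay", "az", "gx", "gy", "gz"), "imu")
  gps <- read_channel(gps_path, c("t", "lat", "lon", "speed"), "gps")
  structure(
    list(subject_id = subject_id, condition = condition,
         imu = imu, gps = gps, truth = NULL, trajectory = NULL, seed = NA),
    class = "sensor_session"
  )
}

read_channel <- function(path, cols, label) {
  if (!file.exists(path)) stopf("%s log not found: %s", label, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stopf("%s log %s is missing column(s): %s", label, path,
          paste(missing, collapse = ", "))
  if (nrow(df) == 0) stopf("%s log %s has an empty channel", label, path)
  bad <- which(diff(df$t) <= 0)
  if (length(bad) > 0)
    stopf("%s log %s: timestamps not strictly increasing at row %d",
          label, path, bad[1] + 1L)
  df[cols]
}

#' Read and write a subject roster
#'
#' Roster CSVs have columns `subject_id,age,sex,status` with
#' `status` in `{Healthy, MCI}`.
#'
#' @param path CSV path.
#' @return `read_roster()` returns a data frame; `write_roster()` returns the
#'   path invisibly.
#' @export
read_roster <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "status")
  missing <- setdiff(need, names(r))
  if (length(missing) > 0)
    stopf("roster %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  bad <- setdiff(unique(r$status), c("Healthy", "MCI"))
  if (length(bad) > 0)
    stopf("roster %s: unknown status value(s): %s", path,
          paste(bad, collapse = ", "))
  r$subject_id <- as.character(r$subject_id)
  r[need]
}

#' @param roster data frame with the roster columns.
#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort's sessions and manifest to a directory
#'
#' Writes one IMU and one GPS log per (subject, condition), a roster CSV, and
#' a manifest CSV with columns `subject_id,condition,imu_path,gps_path`
#' (paths relative to `dir`).
#'
#' @param cohort a `drive_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "drive_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roster(cohort$roster, file.path(dir, "roster.csv"))
  rows <- lapply(cohort$sessions, function(s) {
    base <- sprintf("%s_%s", s$subject_id, s$condition)
    imu <- sprintf("%s_imu.csv", base)
    gps <- sprintf("%s_gps.csv", base)
    write_sensor_log(s, file.path(dir, imu), file.path(dir, gps))
    data.frame(subject_id = s$subject_id, condition = s$condition,
               imu_path = imu, gps_path = gps, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a session directory
#'
#' @param dir directory written by [write_cohort()].
#' @return a `drive_cohort` (sessions carry no simulation ground truth).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  roster <- read_roster(file.path(dir, "roster.csv"))
  sessions <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    sessions[[paste(m$subject_id, m$condition, sep = ".")]] <-
      read_sensor_log(file.path(dir, m$imu_path), file.path(dir, m$gps_path),
                      subject_id = as.character(m$subject_id),
                      condition = m$condition)
  }
  structure(list(roster = roster, sessions = sessions, profiles = NULL,
                 config = NULL, seed = NA),
            class = "drive_cohort")
}

#' Synchronize GPS speed onto the gyroscope timeline
#'
#' The GPS stream (1 Hz) is linearly interpolated onto the IMU timeline
#' (10 Hz) so each yaw-rate sample has an aligned speed. IMU timestamps
#' outside the GPS span take the nearest edge value (clamp policy).
#'
#' @param session a `sensor_session` with at least 2 GPS samples.
#' @return object of class `synced_trace`: list with `t` (IMU timestamps,
#'   s), `gz` (yaw rate, rad/s) and `speed` (interpolated GPS speed, m/s),
#'   all the same length.
#' @export
synchronize_gps <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  if (nrow(session$gps) < 2)
    stopf("need at least 2 GPS samples to interpolate, got %d",
          nrow(session$gps))
  sp <- stats::approx(session$gps$t, session$gps$speed,
                      xout = session$imu$t, rule = 2)$y
  structure(list(t = session$imu$t, gz = session$imu$gz, speed = sp),
            class = "synced_trace")
}

#' @export
print.synced_trace <- function(x, ...) {
  cat(sprintf("<synced_trace> %d samples over %.1f s\n",
              length(x$t), max(x$t) - min(x$t)))
  invisible(x)
}
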