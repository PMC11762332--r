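#' The 26-feature schema
#'
#' The per-subject feature vector summarizes turn kinematics as means over
#' detected events, per turn type and driving condition:
#' features 1–6 are mean |peak yaw rate| (rad/s), 7–18 the means of per-turn
#' maximum and minimum angular acceleration (rad/s^2), 19–24 mean turn speed
#' (m/s), and 25–26 mean U-turn duration (s). Condition/turn-type order is
#' fixed: normal before aggressive; left, right, U-turn.
#'
#' @return data frame with columns `index`, `name`, `quantity`, `condition`,
#'   `turn_type`, `stat`, `unit`.
#' @export
feature_schema <- function() {
  conds <- c("normal", "aggressive")
  types <- c("left90", "right90", "uturn")
  lab <- c(left90 = "left", right90 = "right", uturn = "uturn")

  rows <- list()
  add <- function(quantity, condition, turn_type, stat, unit) {
    i <- length(rows) + 1L
    rows[[i]] <<- data.frame(
      index = i,
      name = sprintf("f%02d_%s_%s_%s%s", i, quantity, condition,
                     lab[[turn_type]], if (stat == "") "" else paste0("_", stat)),
      quantity = quantity, condition = condition, turn_type = turn_type,
      stat = stat, unit = unit, stringsAsFactors = FALSE
    )
  }
  for (cond in conds) for (ty in types) add("yawvel", cond, ty, "", "rad/s")
  for (cond in conds) for (ty in types) {
    add("yawacc", cond, ty, "max", "rad/s^2")
    add("yawacc", cond, ty, "min", "rad/s^2")
  }
  for (cond in conds) for (ty in types) add("speed", cond, ty, "", "m/s")
  for (cond in conds) add("duration", cond, "uturn", "", "s")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the 26-feature vector for one subject
#'
#' Runs turn detection on each of the subject's sessions, excludes minor
#' turns, pools events, and fills each feature slot with the mean of the
#' per-event quantity over all events matching the slot's (condition,
#' turn type). Angular-velocity features use |peak yaw rate| so left and
#' right turns are comparable; the turn direction lives in the type. Slots
#' with no matching events are `NA` and flagged in the missing mask.
#'
#' @param sessions list of `sensor_session` for one subject (typically one
#'   per condition).
#' @param params [detection_params()].
#' @return object of class `feature_vector`: named numeric of length 26 with
#'   attributes `missing` (logical mask), `subject_id` and `n_events`.
#' @export
extract_features <- function(sessions, params = detection_params()) {
  if (inherits(sessions, "sensor_session")) sessions <- list(sessions)
  schema <- feature_schema()
  events <- do.call(rbind, lapply(sessions, function(s) {
    exclude_minor_turns(detect_turn_events(s, params))
  }))
  if (is.null(events)) events <- empty_events()

  vals <- rep(NA_real_, nrow(schema))
  for (i in seq_len(nrow(schema))) {
    sl <- schema[i, ]
    e <- events[events$condition == sl$condition &
                events$turn_type == sl$turn_type, , drop = FALSE]
    if (nrow(e) == 0) next
    vals[i] <- switch(sl$quantity,
      yawvel = mean(abs(e$peak_omega)),
      yawacc = if (sl$stat == "max") mean(e$alpha_max) else mean(e$alpha_min),
      speed = mean(e$mean_speed),
      duration = mean(e$duration)
    )
  }
  structure(stats::setNames(vals, schema$name),
            missing = is.na(vals),
            subject_id = sessions[[1]]$subject_id,
            n_events = nrow(events),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> subject %s: %d/26 populated (%d events)\n",
              attr(x, "subject_id"), sum(!attr(x, "missing")),
              attr(x, "n_events")))
  print(unclass(x)[!attr(x, "missing")])
  invisible(x)
}

#' Build the per-subject feature table for a cohort
#'
#' @param cohort a `drive_cohort` (simulated or read from disk).
#' @param params [detection_params()].
#' @return data frame with columns `subject_id`, `status`, `f01`..`f26`, and
#'   `missing_mask` (26-character 0/1 string in feature order).
#' @export
extract_feature_table <- function(cohort, params = detection_params()) {
  stopifnot(inherits(cohort, "drive_cohort"))
  roster <- cohort$roster
  schema <- feature_schema()
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    sid <- roster$subject_id[i]
    subj_sessions <- Filter(function(s) s$subject_id == sid, cohort$sessions)
    fv <- extract_features(subj_sessions, params)
    row <- as.data.frame(as.list(unclass(fv)))
    names(row) <- sprintf("f%02d", schema$index)
    cbind(data.frame(subject_id = sid, status = roster$status[i],
                     stringsAsFactors = FALSE),
          row,
          data.frame(missing_mask = paste(as.integer(attr(fv, "missing")),
                                          collapse = "")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table CSV
#'
#' One row per subject: `subject_id,status,f01..f26,missing_mask`.
#'
#' @param features data frame from [extract_feature_table()].
#' @param path CSV path.
#' @return `read_feature_table()` returns the data frame; the writer returns
#'   the path invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(missing_mask = "character"))
  need <- c("subject_id", "status", sprintf("f%02d", 1:26))
  missing <- setdiff(need, names(f))
  if (length(missing) > 0)
    stopf("feature table %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  f$subject_id <- as.character(f$subject_id)
  f
}

# numeric feature matrix (subjects x 26) from a feature table
feature_matrix <- function(features) {
  m <- as.matrix(features[, sprintf("f%02d", 1:26)])
  rownames(m) <- features$subject_id
  m
}
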