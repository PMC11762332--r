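#' Turn-detection parameters
#'
#' @param threshold rad/s; minimum |yaw rate| for a peak to count as a turn.
#' @param min_separation_s seconds; minimum spacing between accepted peaks.
#' @param boundary_frac window bounds are placed where |yaw rate| falls below
#'   this fraction of the peak amplitude (or at the midpoint to the adjacent
#'   accepted peak, whichever is tighter).
#' @param left_positive sign convention: `TRUE` (default) means a left turn is
#'   positive yaw (right-handed frame, Z up); set `FALSE` for sensors mounted
#'   upside down.
#' @param smooth_s seconds; width of the centered moving average applied to
#'   the yaw-rate channel before peak analysis (suppresses the upward bias of
#'   single-sample peak amplitudes under sensor noise). 0 disables smoothing.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(threshold = 0.15, min_separation_s = 2,
                             boundary_frac = 0.1, left_positive = TRUE,
                             smooth_s = 0.5) {
  stopifnot(threshold > 0, min_separation_s >= 0,
            boundary_frac > 0, boundary_frac < 1, smooth_s >= 0)
  structure(list(threshold = threshold, min_separation_s = min_separation_s,
                 boundary_frac = boundary_frac, left_positive = left_positive,
                 smooth_s = smooth_s),
            class = "detection_params")
}

# centered moving average with shrinking edge windows; width from seconds
smooth_yaw <- function(gz, t, smooth_s) {
  if (smooth_s <= 0 || length(gz) < 3) return(gz)
  dt <- stats::median(diff(t))
  half <- floor(smooth_s / dt / 2)
  if (half < 1) return(gz)
  n <- length(gz)
  cs <- cumsum(c(0, gz))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect turn-maneuver peaks in a yaw-rate trace
#'
#' A turning maneuver appears as a contiguous excursion of |yaw rate| above
#' the detection threshold. Each excursion (split where the yaw-rate sign
#' flips, so back-to-back opposite turns are never merged) contributes one
#' candidate peak — the sample of maximal |yaw rate|, with plateaus resolved
#' to their midpoint. Candidates closer together than the minimum separation
#' are thinned greedily, largest amplitude first. A window is then placed
#' around each accepted peak: bounds extend outward until |yaw rate| drops
#' below `boundary_frac` of the peak amplitude, clipped at the midpoint to
#' the adjacent accepted peak, so windows never overlap.
#'
#' @param trace a [synchronize_gps()] result (or any list with `t`, `gz`,
#'   `speed`).
#' @param params a [detection_params()].
#' @return list of `turn_window` objects (`start_idx`, `peak_idx`,
#'   `end_idx` into the trace); empty list if no peak clears the threshold.
#' @export
detect_turn_peaks <- function(trace, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  a <- abs(trace$gz)
  n <- length(a)
  if (n == 0) stopf("trace is empty")
  if (n < 3) return(list())

  # suprathreshold excursions, split at sign changes of the yaw rate
  above <- a > params$threshold
  grp <- cumsum(c(TRUE, diff(above) != 0 |
                        sign(trace$gz[-1]) != sign(trace$gz[-n])))
  runs <- Filter(function(g) above[g[1]], split(seq_len(n), grp))
  if (length(runs) == 0) return(list())

  # merge same-sign excursions separated by less than the minimum peak
  # separation: threshold flutter on a long turn ramp must not split the
  # maneuver into fragments
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      gap <- trace$t[r[1]] - trace$t[last[length(last)]]
      same_sign <- sign(trace$gz[r[1]]) == sign(trace$gz[last[length(last)]])
      if (same_sign && gap < params$min_separation_s) {
        merged[[length(merged)]] <- c(last[1]:r[length(r)])
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
  }

  cand <- vapply(merged, function(g) {
    mx <- max(a[g])
    hits <- g[a[g] == mx]
    hits[(length(hits) + 1L) %/% 2L]  # plateau midpoint
  }, integer(1))

  # greedy acceptance by descending amplitude under the separation constraint
  cand <- cand[order(-a[cand], cand)]
  accepted <- integer(0)
  for (p in cand) {
    if (all(abs(trace$t[p] - trace$t[accepted]) >= params$min_separation_s))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)

  windows <- vector("list", length(accepted))
  for (k in seq_along(accepted)) {
    p <- accepted[k]
    level <- params$boundary_frac * a[p]
    lo <- if (k > 1) as.integer(ceiling((accepted[k - 1] + p) / 2)) else 1L
    hi <- if (k < length(accepted)) as.integer(floor((accepted[k + 1] + p) / 2)) else n
    s <- p
    while (s > lo && a[s - 1L] >= level) s <- s - 1L
    e <- p
    while (e < hi && a[e + 1L] >= level) e <- e + 1L
    windows[[k]] <- structure(
      list(start_idx = s, peak_idx = p, end_idx = e),
      class = "turn_window"
    )
  }
  windows
}

#' Classify a detected window by integrated turn angle
#'
#' Integrates yaw rate over the window (trapezoidal rule). |angle| of at
#' least 135 degrees is a U-turn; between 45 and 135 degrees a 90-degree turn
#' whose direction follows the sign convention; below 45 degrees a minor turn
#' (excluded downstream).
#'
#' @param window a `turn_window`.
#' @param trace the trace the window indexes into.
#' @param params [detection_params()] (sign convention).
#' @return list with `turn_type` (`"left90"`, `"right90"`, `"uturn"` or
#'   `"minor"`) and `integrated_angle` (rad, signed).
#' @export
classify_turn <- function(window, trace, params = detection_params()) {
  idx <- window$start_idx:window$end_idx
  ang <- trapz(trace$t[idx], trace$gz[idx])
  signed <- if (params$left_positive) ang else -ang
  aa <- abs(signed)
  type <- if (aa >= 3 * pi / 4) "uturn"
  else if (aa >= pi / 4) { if (signed > 0) "left90" else "right90" }
  else "minor"
  list(turn_type = type, integrated_angle = ang)
}

#' Angular acceleration extrema over a turn window
#'
#' Discrete-derivative angular acceleration: consecutive-sample differences
#' of yaw rate divided by the sampling interval. Returns the extrema over the
#' window.
#'
#' @param omega yaw-rate samples over the window (rad/s).
#' @param t their timestamps (s); consecutive spacing is used as the
#'   denominator.
#' @return named numeric `c(alpha_max, alpha_min)` in rad/s^2.
#' @export
compute_angular_acceleration <- function(omega, t) {
  if (length(omega) < 2)
    stopf("angular acceleration needs at least 2 samples, got %d", length(omega))
  if (length(t) != length(omega)) stopf("omega and t lengths differ")
  alpha <- diff(omega) / diff(t)
  c(alpha_max = max(alpha), alpha_min = min(alpha))
}

#' Mean GPS speed over a turn window
#'
#' @param window a `turn_window`.
#' @param trace a `synced_trace`.
#' @return mean interpolated speed over the window, m/s.
#' @export
turn_speed <- function(window, trace) {
  mean(trace$speed[window$start_idx:window$end_idx])
}

#' Detect and characterize all turn events in a session
#'
#' Full per-session pipeline: synchronize GPS onto the gyro timeline, smooth
#' the yaw-rate channel (see `smooth_s` in [detection_params()]), detect
#' peaks, classify each window, and compute per-event kinematics. All
#' yaw-derived quantities (peak amplitude, integrated angle, angular
#' acceleration) are taken from the smoothed channel; speed comes from the
#' synchronized GPS stream.
#'
#' @param session a `sensor_session`.
#' @param params [detection_params()].
#' @param condition condition label to attach; defaults to the session's.
#' @return data frame with one row per detected event: `turn_type`,
#'   `condition`, `peak_omega` (signed rad/s), `alpha_max`, `alpha_min`
#'   (rad/s^2), `mean_speed` (m/s), `duration` (s), `integrated_angle` (rad),
#'   plus window indices/times.
#' @export
detect_turn_events <- function(session, params = detection_params(),
                               condition = session$condition) {
  trace <- synchronize_gps(session)
  trace$gz <- smooth_yaw(trace$gz, trace$t, params$smooth_s)
  windows <- detect_turn_peaks(trace, params)
  if (length(windows) == 0) return(empty_events())
  rows <- lapply(windows, function(w) {
    idx <- w$start_idx:w$end_idx
    cls <- classify_turn(w, trace, params)
    al <- compute_angular_acceleration(trace$gz[idx], trace$t[idx])
    data.frame(
      turn_type = cls$turn_type,
      condition = condition,
      peak_omega = trace$gz[w$peak_idx],
      alpha_max = al[["alpha_max"]],
      alpha_min = al[["alpha_min"]],
      mean_speed = turn_speed(w, trace),
      duration = trace$t[w$end_idx] - trace$t[w$start_idx],
      integrated_angle = cls$integrated_angle,
      start_idx = w$start_idx, peak_idx = w$peak_idx, end_idx = w$end_idx,
      start_t = trace$t[w$start_idx], end_t = trace$t[w$end_idx],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(turn_type = character(0), condition = character(0),
             peak_omega = numeric(0), alpha_max = numeric(0),
             alpha_min = numeric(0), mean_speed = numeric(0),
             duration = numeric(0), integrated_angle = numeric(0),
             start_idx = integer(0), peak_idx = integer(0),
             end_idx = integer(0), start_t = numeric(0), end_t = numeric(0),
             stringsAsFactors = FALSE)
}

#' Exclude minor turns
#'
#' Removes events classified as minor (integrated angle below 45 degrees,
#' e.g., small steering adjustments within U-turns) and any event whose
#' window lies entirely within an enclosing U-turn window. Order is
#' preserved.
#'
#' @param events data frame from [detect_turn_events()].
#' @return filtered events data frame.
#' @export
exclude_minor_turns <- function(events) {
  if (nrow(events) == 0) return(events)
  keep <- events$turn_type != "minor"
  ut <- events[events$turn_type == "uturn", , drop = FALSE]
  if (nrow(ut) > 0) {
    for (i in which(keep)) {
      if (events$turn_type[i] == "uturn") next
      inside <- any(events$start_t[i] >= ut$start_t &
                    events$end_t[i] <= ut$end_t)
      if (inside) keep[i] <- FALSE
    }
  }
  events[keep, , drop = FALSE]
}
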