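#' Build a closed driving circuit
#'
#' Constructs the standardized assessment circuit: an ordered sequence of
#' straight sections and turn segments (90-degree left/right turns and
#' 180-degree U-turns) forming a closed loop. The default composition is two
#' U-turns (radius 8 m, both in the same direction so headings close at
#' \eqn{+2\pi}), two left and two right 90-degree turns (radius 10 m), with
#' six straight sections padded so one lap measures exactly
#' `lap_length_m` (540 m by default).
#'
#' Sign convention: a left turn is positive yaw (right-handed frame, Z up).
#'
#' @param lap_length_m total arc length of one lap in meters.
#' @param laps number of laps driven per session.
#' @param n_left,n_right,n_uturn number of left 90-degree, right 90-degree and
#'   U-turn segments per lap.
#' @param radius_90_m,radius_uturn_m turn radii in meters.
#' @param uturn_direction `"left"` or `"right"`; all U-turns share a direction
#'   so that signed heading changes close at \eqn{\pm 2\pi} per lap.
#' @return An object of class `circuit_spec`: a list with `segments`
#'   (data frame with columns `kind`, `length_m`, `radius_m`, `angle_rad`),
#'   `lap_length_m` and `laps`.
#' @examples
#' circ <- build_circuit()
#' circ$lap_length_m            # 540
#' sum(circ$segments$angle_rad) # 2 * pi
#' @export
build_circuit <- function(lap_length_m = 540, laps = 10,
                          n_left = 2, n_right = 2, n_uturn = 2,
                          radius_90_m = 10, radius_uturn_m = 8,
                          uturn_direction = c("left", "right")) {
  uturn_direction <- match.arg(uturn_direction)
  if (laps < 1) stopf("laps must be >= 1, got %s", laps)
  if (n_left < 0 || n_right < 0 || n_uturn < 0)
    stopf("turn counts must be nonnegative")
  n_turns <- n_left + n_right + n_uturn
  if (n_turns == 0)
    stopf("circuit needs at least one turn: heading cannot close without turns")

  u_sign <- if (uturn_direction == "left") 1 else -1
  heading_sum <- n_left * pi / 2 - n_right * pi / 2 + u_sign * n_uturn * pi
  if (abs(abs(heading_sum) - 2 * pi) > 1e-9)
    stopf(paste0("requested turns do not close the loop: signed heading sum ",
                 "is %.4f rad, need +/- 2*pi"), heading_sum)

  arc_90 <- (pi / 2) * radius_90_m
  arc_u <- pi * radius_uturn_m
  turn_arc_total <- (n_left + n_right) * arc_90 + n_uturn * arc_u
  if (turn_arc_total > lap_length_m)
    stopf(paste0("infeasible geometry: turn arcs total %.1f m but the lap is ",
                 "only %.1f m (deficit %.1f m)"),
          turn_arc_total, lap_length_m, turn_arc_total - lap_length_m)

  # round-robin turn order (spreads turn types around the lap)
  pool <- c(left90 = n_left, uturn = n_uturn, right90 = n_right)
  turn_kinds <- character(0)
  while (sum(pool) > 0) {
    for (k in names(pool)) {
      if (pool[[k]] > 0) {
        turn_kinds <- c(turn_kinds, k)
        pool[[k]] <- pool[[k]] - 1
      }
    }
  }

  straight_total <- lap_length_m - turn_arc_total
  straight_each <- straight_total / n_turns

  rows <- list()
  for (k in turn_kinds) {
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "straight", length_m = straight_each,
                 radius_m = NA_real_, angle_rad = 0)
    rows[[length(rows) + 1L]] <- switch(
      k,
      left90 = data.frame(kind = "left90", length_m = arc_90,
                          radius_m = radius_90_m, angle_rad = pi / 2),
      right90 = data.frame(kind = "right90", length_m = arc_90,
                           radius_m = radius_90_m, angle_rad = -pi / 2),
      uturn = data.frame(kind = "uturn", length_m = arc_u,
                         radius_m = radius_uturn_m, angle_rad = u_sign * pi)
    )
  }
  segments <- do.call(rbind, rows)
  rownames(segments) <- NULL

  circ <- structure(
    list(segments = segments, lap_length_m = lap_length_m, laps = laps),
    class = "circuit_spec"
  )
  validate_circuit(circ)
  circ
}

#' Validate a circuit specification
#'
#' Checks the closed-loop invariants: segment arc lengths sum to the lap
#' length (relative tolerance 1e-6), signed heading changes sum to
#' \eqn{\pm 2\pi}, and `laps >= 1`.
#'
#' @param circ a `circuit_spec`.
#' @return `circ`, invisibly; errors if an invariant fails.
#' @export
validate_circuit <- function(circ) {
  stopifnot(inherits(circ, "circuit_spec"))
  seg <- circ$segments
  tot <- sum(seg$length_m)
  if (abs(tot - circ$lap_length_m) > 1e-6 * circ$lap_length_m)
    stopf("segment lengths sum to %.6f m, expected lap length %.6f m",
          tot, circ$lap_length_m)
  hs <- sum(seg$angle_rad)
  if (abs(abs(hs) - 2 * pi) > 1e-9)
    stopf("signed heading changes sum to %.9f rad, expected +/- 2*pi", hs)
  if (circ$laps < 1) stopf("laps must be >= 1")
  invisible(circ)
}

#' @export
print.circuit_spec <- function(x, ...) {
  tab <- table(x$segments$kind)
  cat(sprintf("<circuit_spec> %d laps x %.0f m\n", x$laps, x$lap_length_m))
  cat("  segments per lap:",
      paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}
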