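#' Heading series of a velocity sequence
#'
#' Headings atan2(vn, ve) unwrapped so that consecutive differences lie in
#' (-pi, pi]: a bird circling steadily accumulates heading monotonically
#' without 2 pi jumps. Windows containing near-zero speeds have undefined
#' headings and are rejected (returned as NULL, a rejection signal rather
#' than an error, so the segment scan can move on).
#'
#' @param ve,vn east/north velocity components (m s^-1), length >= 2.
#' @param min_speed speeds at or below this (m s^-1) reject the window.
#'   The default 0.5 m s^-1 is far below any plausible soaring speed.
#' @return unwrapped headings in radians, or NULL when rejected.
#' @export
heading_series <- function(ve, vn, min_speed = 0.5) {
  stopifnot(length(ve) >= 2, length(ve) == length(vn))
  if (any(sqrt(ve^2 + vn^2) <= min_speed)) return(NULL)
  h <- atan2(vn, ve)
  d <- diff(h)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(h[1], d))
}

# Signed cumulative turn over a 31-fix window, de-biased for the
# half-sample phase offset of the one-sided end differences: the first and
# last finite-difference headings sit at t = 0.5 and 29.5 s, so the raw
# heading span covers only 29 of the 30 s and is scaled by 30/29.
cumulative_turn <- function(headings, duration = 30) {
  (headings[length(headings)] - headings[1]) * duration / (duration - 1)
}

#' Find full-circle thermalling segments in a track
#'
#' Scans each 1 Hz burst left to right for 31-fix / 30 s windows in which
#' the bird completes at least one full circle: the unwrapped ground-velocity
#' heading turns by at least 2 pi in magnitude and every speed exceeds
#' `min_speed`. Accepted windows tile the track in contiguous 30 s
#' intervals (consecutive segments share one boundary fix); after an
#' accepted window the scan resumes at its last fix, otherwise it advances
#' one fix. Segments never cross burst boundaries and the scan is
#' deterministic.
#'
#' @param track a `soar_track` from [read_track()] or the simulator.
#' @param min_speed rejection gate on per-fix ground speed (m s^-1).
#' @return list of `loop_segment` objects, in time order. Each carries the
#'   projected window, the 31 ground velocities, the signed de-biased
#'   cumulative turn (radians), turn direction (+1 counterclockwise /
#'   -1 clockwise), duration (30 s), mean altitude, mean per-fix air density
#'   (NA if any fix lacks one), climb rate over the window, and ids.
#'   Attribute `windows_scanned` counts candidate windows examined.
#' @export
find_loop_segments <- function(track, min_speed = 0.5) {
  stopifnot(is.data.frame(track))
  segs <- list()
  scanned <- 0L
  sid <- 0L
  for (b in unique(track$burst)) {
    fx <- track[track$burst == b, , drop = FALSE]
    n <- nrow(fx)
    if (n < 31) next
    i <- 1L
    while (i + 30L <= n) {
      scanned <- scanned + 1L
      win <- fx[i:(i + 30L), , drop = FALSE]
      pw <- project_window(win)
      vel <- ground_velocity(pw)
      h <- heading_series(vel$ve, vel$vn, min_speed = min_speed)
      turn <- if (is.null(h)) 0 else cumulative_turn(h)
      if (!is.null(h) && abs(turn) >= 2 * pi) {
        sid <- sid + 1L
        rho <- win$air_density
        segs[[sid]] <- structure(list(
          segment_id = sid,
          individual = win$individual[1],
          burst = b,
          start = win$timestamp[1],
          window = pw,
          velocities = vel,
          cumulative_turn = turn,
          duration = 30,
          turn_direction = if (turn >= 0) 1L else -1L,
          mean_altitude = mean(win$altitude),
          air_density = if (anyNA(rho)) NA_real_ else mean(rho),
          vertical_speed = (win$altitude[31] - win$altitude[1]) / 30
        ), class = "loop_segment")
        i <- i + 30L   # next window starts at this window's last fix
      } else {
        i <- i + 1L
      }
    }
  }
  structure(segs, windows_scanned = scanned)
}

#' Angular rate of a loop segment
#'
#' omega = |cumulative turn| / 30 s, the mean magnitude of the turning rate
#' across the window. The turn direction is carried separately on the
#' segment so clockwise and counterclockwise circles are treated
#' symmetrically.
#'
#' @param segment a `loop_segment`.
#' @return angular rate (rad s^-1), strictly positive.
#' @export
angular_rate <- function(segment) {
  stopifnot(inherits(segment, "loop_segment"))
  abs(segment$cumulative_turn) / segment$duration
}

#' @export
print.loop_segment <- function(x, ...) {
  cat(sprintf(
    "loop segment %d (%s): start %s, turn %.1f deg (%s), alt %.0f m\n",
    x$segment_id, x$individual, format(x$start, tz = "UTC"),
    x$cumulative_turn * 180 / pi,
    if (x$turn_direction > 0) "ccw" else "cw", x$mean_altitude))
  invisible(x)
}

#' Tabulate loop segments
#'
#' One row per segment with the quantities reported in segment tables:
#' start time, mean altitude, cumulative turn (degrees) and angular rate.
#'
#' @param segments list from [find_loop_segments()].
#' @return data frame.
#' @export
segments_table <- function(segments) {
  if (length(segments) == 0)
    return(data.frame(segment_id = integer(), individual = character(),
                      start_time = character(), mean_altitude = numeric(),
                      cumulative_turn_deg = numeric(),
                      omega_rad_s = numeric()))
  do.call(rbind, lapply(segments, function(s) data.frame(
    segment_id = s$segment_id, individual = s$individual,
    start_time = format(s$start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    mean_altitude = s$mean_altitude,
    cumulative_turn_deg = s$cumulative_turn * 180 / pi,
    omega_rad_s = angular_rate(s), stringsAsFactors = FALSE)))
}
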