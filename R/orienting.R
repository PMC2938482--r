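# Head-orienting response analysis: angle trajectories from x-y marker
# coordinates, movement latency by the three-consecutive-frames rule, final
# bearing as the circular mean of the last frames, and condition comparison.

# Bearing of a displacement vector in the arena convention:
# 0 deg along +y, positive clockwise (rightward, toward +x).
bearing_deg <- function(dx, dy) atan2(dx, dy) * 180 / pi

#' Angle series of an orienting trajectory
#'
#' Converts marker coordinates to a per-frame heading: the bearing of each
#' frame-to-frame displacement vector, measured relative to the initial
#' heading and wrapped to (-180, 180]. The initial heading is the bearing of
#' the mean displacement over the last `pre_frames` pre-onset frames; if the
#' marker is effectively stationary before onset (the expected case with the
#' animal at the start spout) it falls back to the arena 0-degree axis, or to
#' `initial_heading_deg` if supplied. Frames with negligible displacement
#' carry the previous frame's angle forward (the head has not moved).
#'
#' @param traj a [trajectory()].
#' @param pre_frames pre-onset frames used to estimate the initial heading.
#' @param static_tol displacement (arena units) below which a frame counts as
#'   stationary.
#' @param initial_heading_deg optional override of the initial heading.
#' @return numeric vector of angles (degrees), one per frame; zero until the
#'   first movement.
#' @export
angles_from_xy <- function(traj, pre_frames = 5, static_tol = 1e-9,
                           initial_heading_deg = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames
  n <- nrow(fr)
  if (n < 2) stop("need at least 2 frames")
  if (is.null(initial_heading_deg)) {
    i1 <- max(2, traj$onset_index - pre_frames)
    i2 <- traj$onset_index
    dx <- fr$x[i2] - fr$x[i1 - 1]
    dy <- fr$y[i2] - fr$y[i1 - 1]
    if (sqrt(dx^2 + dy^2) < static_tol) {
      heading <- 0  # stationary at the spout: arena 0-degree axis
    } else {
      heading <- bearing_deg(dx, dy)
    }
  } else {
    heading <- initial_heading_deg
  }
  dx <- diff(fr$x)
  dy <- diff(fr$y)
  step <- sqrt(dx^2 + dy^2)
  ang <- numeric(n)
  for (i in 2:n) {
    if (step[i - 1] < static_tol) {
      ang[i] <- ang[i - 1]
    } else {
      ang[i] <- wrap_angle(bearing_deg(dx[i - 1], dy[i - 1]) - heading)
    }
  }
  ang
}

#' Movement latency by the three-consecutive-frames rule
#'
#' The latency is the time (after stimulus onset) of the third frame of three
#' consecutive frames that each changed by at least `move_threshold_deg` in
#' the same direction. Returns `NA` if no such triplet exists: absence of a
#' response is a value, not an error.
#'
#' @param angles angle series from [angles_from_xy()].
#' @param onset_index 1-based stimulus-onset frame.
#' @param move_threshold_deg per-frame movement criterion, degrees.
#' @param fps frame rate.
#' @return latency in ms, or `NA_real_`.
#' @export
detect_latency <- function(angles, onset_index, move_threshold_deg = 1,
                           fps = 60) {
  n <- length(angles)
  if (n < onset_index + 3) stop("series must extend at least 3 frames past onset")
  d <- diff(angles)
  for (k in (onset_index + 3):n) {
    dd <- d[(k - 3):(k - 1)]  # changes into frames k-2, k-1, k
    if (all(abs(dd) >= move_threshold_deg) &&
        (all(dd > 0) || all(dd < 0))) {
      return((k - onset_index) / fps * 1000)
    }
  }
  NA_real_
}

#' Final bearing of an orienting response
#'
#' Circular (unit-vector) mean of the last `n_frames` angles of the recorded
#' second, robust to wraparound at +/-180 degrees.
#'
#' @param angles angle series (degrees).
#' @param n_frames number of terminal frames to average (default 3).
#' @return mean bearing in degrees, wrapped to (-180, 180].
#' @export
final_bearing <- function(angles, n_frames = 3) {
  if (length(angles) < n_frames) stop("fewer than ", n_frames, " frames")
  last <- utils::tail(angles, n_frames) * pi / 180
  wrap_angle(atan2(mean(sin(last)), mean(cos(last))) * 180 / pi)
}

#' Analyze one trajectory into an orienting result
#'
#' @param traj a [trajectory()].
#' @param move_threshold_deg per-frame movement criterion, degrees.
#' @param ... passed to [angles_from_xy()].
#' @return object of class `orienting_result`: `latency_ms` (may be `NA`),
#'   `final_bearing_deg`, `direction` (`"left"`/`"right"`/`"none"`).
#' @export
analyze_orienting <- function(traj, move_threshold_deg = 1, ...) {
  ang <- angles_from_xy(traj, ...)
  lat <- detect_latency(ang, traj$onset_index, move_threshold_deg, traj$fps)
  fb <- final_bearing(ang)
  structure(list(latency_ms = lat, final_bearing_deg = fb,
                 direction = if (fb > 0) "right" else if (fb < 0) "left" else "none"),
            class = "orienting_result")
}

#' Compare orienting results between two recording conditions
#'
#' Differences of condition means (a minus b); trials with an absent latency
#' are excluded from the latency mean only.
#'
#' @param results_a,results_b non-empty lists of `orienting_result` (e.g. head
#'   marker vs jacket marker trials).
#' @return list: `latency_diff_ms`, `bearing_diff_deg`, `mean_latency_a`,
#'   `mean_latency_b`, `mean_bearing_a`, `mean_bearing_b`.
#' @export
compare_conditions <- function(results_a, results_b) {
  if (length(results_a) == 0 || length(results_b) == 0) stop("empty condition")
  lat <- function(rs) {
    v <- vapply(rs, function(r) r$latency_ms, numeric(1))
    mean(v[!is.na(v)])
  }
  brg <- function(rs) mean(vapply(rs, function(r) r$final_bearing_deg, numeric(1)))
  la <- lat(results_a); lb <- lat(results_b)
  ba <- brg(results_a); bb <- brg(results_b)
  list(latency_diff_ms = la - lb, bearing_diff_deg = ba - bb,
       mean_latency_a = la, mean_latency_b = lb,
       mean_bearing_a = ba, mean_bearing_b = bb)
}
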