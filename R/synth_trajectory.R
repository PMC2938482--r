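# Synthetic head/jacket orienting trajectories: x-y marker coordinates at
# video frame rate tracing a sigmoid angular sweep from straight ahead to a
# final bearing, with configurable movement latency.

#' Configuration for a synthetic orienting trajectory
#'
#' The marker is stationary before stimulus onset (the animal holds the start
#' spout), then sweeps to `final_bearing_deg` along a raised-cosine (sigmoid)
#' angular profile. `latency_ms` follows the video-scoring convention used for
#' orienting responses: it is the time of the third of three consecutive
#' moving frames, so the first above-threshold frame-to-frame movement occurs
#' two frames earlier. It must therefore be at least `3/fps` seconds.
#'
#' @param latency_ms movement latency under the three-frame rule, ms.
#' @param final_bearing_deg asymptotic bearing, degrees (positive = right).
#' @param fps frame rate, frames/s.
#' @param duration_s post-onset recording duration, s.
#' @param pre_onset_s stationary pre-onset segment, s.
#' @param rise_time_ms duration of the angular sweep, ms.
#' @param speed_units_s marker speed while moving, arena units/s.
#' @param tracker_noise_deg sd of per-frame direction jitter, degrees.
#' @param seed integer RNG seed.
#' @return object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(latency_ms = 200,
                                  final_bearing_deg = 45,
                                  fps = 60,
                                  duration_s = 1,
                                  pre_onset_s = 0.25,
                                  rise_time_ms = 150,
                                  speed_units_s = 0.25,
                                  tracker_noise_deg = 0,
                                  seed = 1) {
  if (fps <= 0) stop("fps must be > 0")
  if (latency_ms < 0 || latency_ms >= duration_s * 1000) {
    stop("latency_ms must lie in [0, duration_s * 1000)")
  }
  if (latency_ms < 3000 / fps) {
    stop("latency_ms must be at least 3 frame periods (three-frame rule)")
  }
  if (latency_ms + rise_time_ms >= duration_s * 1000) {
    stop("sweep must finish inside the recorded second")
  }
  structure(as.list(environment()), class = "trajectory_sim_config")
}

#' Container for a tracked marker trajectory
#'
#' @param frames data.frame with columns `frame`, `t_s`, `x`, `y` at
#'   `1/fps` spacing.
#' @param onset_index 1-based frame index of stimulus onset.
#' @param fps frames per second.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, onset_index, fps) {
  stopifnot(all(c("frame", "t_s", "x", "y") %in% names(frames)))
  if (onset_index < 1 || onset_index > nrow(frames)) {
    stop("onset_index outside the recorded frames")
  }
  dt <- diff(frames$t_s)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  structure(list(frames = frames, onset_index = onset_index, fps = fps),
            class = "trajectory")
}

# Angular profile at post-onset frame i (frames after onset): 0 before the
# sweep, raised-cosine rise to B, then constant. The first moving frame is
# placed so the third consecutive moving frame falls at latency_ms.
trajectory_angle_profile <- function(cfg, i) {
  lat_frames <- round(cfg$latency_ms * cfg$fps / 1000)
  n_rise <- max(3, round(cfg$rise_time_ms * cfg$fps / 1000))
  start <- lat_frames - 3   # frame index where the angle is still 0
  k <- pmin(pmax(i - start, 0), n_rise)
  cfg$final_bearing_deg * (1 - cos(pi * k / n_rise)) / 2
}

#' Simulate an orienting-response trajectory
#'
#' The marker is stationary for `pre_onset_s`, then (after the configured
#' latency) moves at constant speed while its heading follows the sigmoid
#' angle profile; after the sweep it continues straight along the final
#' bearing. Bearings use the arena convention: 0 deg along +y, positive
#' clockwise (rightward, toward +x). With `tracker_noise_deg = 0` the heading
#' series is monotone after onset.
#'
#' @param cfg a [trajectory_sim_config()].
#' @return a [trajectory()].
#' @export
simulate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "trajectory_sim_config"))
  n_pre <- round(cfg$pre_onset_s * cfg$fps)
  n_post <- round(cfg$duration_s * cfg$fps)
  n <- n_pre + 1 + n_post
  onset_index <- n_pre + 1
  post_i <- seq_len(n_post)
  theta <- trajectory_angle_profile(cfg, post_i)
  step_dir <- theta
  if (cfg$tracker_noise_deg > 0) {
    step_dir <- with_fixed_seed(cfg$seed, {
      theta + stats::rnorm(n_post, sd = cfg$tracker_noise_deg)
    })
  }
  start <- round(cfg$latency_ms * cfg$fps / 1000) - 3
  moving <- post_i > start & cfg$final_bearing_deg != 0
  step_len <- ifelse(moving, cfg$speed_units_s / cfg$fps, 0)
  dx <- step_len * sin(step_dir * pi / 180)
  dy <- step_len * cos(step_dir * pi / 180)
  x <- c(rep(0, n_pre + 1), cumsum(dx))
  y <- c(rep(0, n_pre + 1), cumsum(dy))
  frames <- data.frame(
    frame = seq_len(n),
    t_s = (seq_len(n) - 1) / cfg$fps,
    x = x, y = y
  )
  trajectory(frames, onset_index, cfg$fps)
}
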