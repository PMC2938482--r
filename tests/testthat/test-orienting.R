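straight_traj <- function(n_pre = 15, n_post = 60, step = c(0, 0.01),
                          fps = 60) {
  # marker at rest, then moving with constant per-frame displacement `step`
  n <- n_pre + 1 + n_post
  dx <- c(rep(0, n_pre), rep(step[1], n_post))
  dy <- c(rep(0, n_pre), rep(step[2], n_post))
  frames <- data.frame(frame = 1:n, t_s = (0:(n - 1)) / fps,
                       x = cumsum(c(0, dx)), y = cumsum(c(0, dy)))
  trajectory(frames, onset_index = n_pre + 1, fps = fps)
}

test_that("angles follow the displacement bearing relative to the initial heading", {
  # straight along the arena axis: all angles zero
  expect_true(all(angles_from_xy(straight_traj()) == 0))
  # straight to the right (east): +90 relative to the north-facing start
  east <- straight_traj(step = c(0.01, 0))
  ang <- angles_from_xy(east)
  expect_equal(utils::tail(ang, 1), 90)
  # quarter-circle ending perpendicular-right: final angle +90
  fps <- 60
  phi <- seq(0, pi / 2, length.out = 61)
  x <- 0.2 * (1 - cos(phi))
  y <- 0.2 * sin(phi)
  frames <- data.frame(frame = 1:71, t_s = (0:70) / fps,
                       x = c(rep(0, 10), x), y = c(rep(0, 10), y))
  qc <- trajectory(frames, onset_index = 10, fps = fps)
  expect_equal(utils::tail(angles_from_xy(qc), 1), 90, tolerance = 0.02)
})

test_that("synthetic sigmoid trajectories round-trip through the angle analysis", {
  cfg <- trajectory_sim_config(latency_ms = 250, final_bearing_deg = 38,
                               tracker_noise_deg = 0)
  traj <- simulate_trajectory(cfg)
  ang <- angles_from_xy(traj)
  i <- traj$onset_index + seq_len(60)
  expect_lt(max(abs(ang[i] - trajectory_angle_profile(cfg, seq_len(60)))), 0.1)
})

test_that("the three-consecutive-frames rule locates movement latency", {
  # flat until 10 frames after onset, then a monotone rise: latency 200 ms
  onset <- 20
  ang <- c(rep(0, onset + 9), cumsum(rep(2, 30)))
  expect_equal(detect_latency(ang, onset, 1, 60), 12 / 60 * 1000)
  # completely flat: absent, not an error
  expect_true(is.na(detect_latency(numeric(60), 20, 1, 60)))
  # sub-threshold jitter then a clean rise: only the clean triplet counts
  jitter <- rep(c(0.4, -0.4), 10)
  ang2 <- c(rep(0, onset), cumsum(jitter), cumsum(rep(2, 10)) + 0)
  lat2 <- detect_latency(ang2, onset, 1, 60)
  expect_equal(lat2, (20 + 3) / 60 * 1000)
  # opposite-direction steps do not form a triplet
  ang3 <- c(rep(0, onset), cumsum(c(2, -2, 2, -2, 2, -2)))
  expect_true(is.na(detect_latency(ang3, onset, 1, 60)))
  expect_error(detect_latency(numeric(10), 9, 1, 60), "3 frames")
})

test_that("noiseless generator latency and bearing are recovered within tolerance", {
  for (lat in c(100, 200, 317)) {
    cfg <- trajectory_sim_config(latency_ms = lat, final_bearing_deg = 42.96,
                                 tracker_noise_deg = 0)
    res <- analyze_orienting(simulate_trajectory(cfg))
    expect_lt(abs(res$latency_ms - lat), 1000 / 60 + 1e-9)  # within one frame
    expect_lt(abs(res$final_bearing_deg - 42.96), 1)
    expect_equal(res$direction, "right")
  }
  # leftward responses carry negative bearings
  left <- analyze_orienting(simulate_trajectory(
    trajectory_sim_config(final_bearing_deg = -42, tracker_noise_deg = 0)))
  expect_lt(abs(left$final_bearing_deg + 42), 1)
  expect_equal(left$direction, "left")
})

test_that("final bearing is a circular mean robust to wraparound", {
  expect_equal(final_bearing(c(0, 0, 40, 42, 44)), 42)
  expect_equal(final_bearing(c(359, 1, 3)), 1)
  expect_equal(final_bearing(c(179, -179, -177)), -179)
  expect_equal(final_bearing(rep(90, 5)), 90)
  expect_error(final_bearing(c(1, 2)), "fewer")
})

test_that("rotating coordinates and the initial heading leaves results unchanged", {
  cfg <- trajectory_sim_config(latency_ms = 200, final_bearing_deg = 35,
                               tracker_noise_deg = 0.3, seed = 5)
  traj <- simulate_trajectory(cfg)
  res0 <- analyze_orienting(traj, initial_heading_deg = 0)
  for (rot in c(30, 117, -64)) {
    r <- rot * pi / 180
    rotated <- traj
    # clockwise rotation by `rot` degrees in the (x = east, y = north) frame
    rotated$frames$x <- traj$frames$x * cos(r) + traj$frames$y * sin(r)
    rotated$frames$y <- -traj$frames$x * sin(r) + traj$frames$y * cos(r)
    res <- analyze_orienting(rotated, initial_heading_deg = rot)
    expect_lt(abs(res$final_bearing_deg - res0$final_bearing_deg), 1e-6)
    expect_equal(res$latency_ms, res0$latency_ms)
  }
})

test_that("condition comparison averages latency over responding trials only", {
  mk <- function(lat, brg) structure(list(latency_ms = lat,
                                          final_bearing_deg = brg,
                                          direction = "right"),
                                     class = "orienting_result")
  a <- list(mk(200, 40), mk(200, 44))
  expect_equal(compare_conditions(a, a)$latency_diff_ms, 0)
  expect_equal(compare_conditions(a, a)$bearing_diff_deg, 0)
  b <- list(mk(300, 41), mk(320, 43))
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$latency_diff_ms, -110)
  expect_equal(cmp$bearing_diff_deg, 0)
  # absent latencies drop from the latency mean, not the bearing mean
  c1 <- list(mk(200, 40), mk(NA_real_, 44))
  cmp2 <- compare_conditions(c1, b)
  expect_equal(cmp2$mean_latency_a, 200)
  expect_equal(cmp2$mean_bearing_a, 42)
  expect_error(compare_conditions(list(), b), "empty")
})
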