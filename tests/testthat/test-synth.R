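test_that("Woodworth geometry matches the closed form, mirrored and odd", {
  a <- 0.0253
  expect_equal(woodworth_itd(90, a), (a / 343) * (1 + pi / 2))
  expect_equal(woodworth_itd(90, a), oracle_woodworth_s(90, a))
  for (th in c(-150, -90, -40, -10, 10, 45, 120, 180)) {
    expect_equal(woodworth_itd(th, a), oracle_woodworth_s(th, a))
    expect_equal(woodworth_itd(-th, a), -woodworth_itd(th, a))
  }
  # rear mirror: 120 deg equals 60 deg
  expect_equal(woodworth_itd(120, a), woodworth_itd(60, a))
})

test_that("simulated IRs carry the model ITD, including the 90-degree maximum", {
  model <- head_model()
  ir90 <- simulate_head_ir(model, 90)
  closed_form_us <- (model$effective_radius / 343) * (1 + pi / 2) * 1e6
  expect_lt(abs(compute_itd(ir90) - closed_form_us), 2)
  ir0 <- simulate_head_ir(model, 0)
  expect_equal(compute_itd(ir0), 0)
  expect_lt(abs(compute_ild(ir0, c(750, 1500))), 1e-6)
  expect_lt(abs(compute_ild(ir0, c(4000, 8000))), 1e-6)
})

test_that("head orientation rotates the cue frame (equivariance)", {
  # source at +40 with head at +40: dead ahead in the head frame
  turned <- head_model(head_orientation = 40)
  ir <- simulate_head_ir(turned, 40)
  expect_equal(compute_itd(ir), 0)
  expect_lt(abs(compute_ild(ir, c(4000, 8000))), 1e-6)
  # orientation h, source theta == orientation 0, source theta - h
  base <- head_model()
  ir_a <- simulate_head_ir(turned, 70)
  ir_b <- simulate_head_ir(base, 30)
  expect_equal(ir_a$left_ir, ir_b$left_ir)
  expect_equal(ir_a$right_ir, ir_b$right_ir)
})

test_that("IR generator contracts: bad fs, angle, or tap count", {
  model <- head_model()
  expect_error(simulate_head_ir(model, 0, fs = -1), "fs")
  expect_error(simulate_head_ir(model, 200), "180")
  expect_error(simulate_head_ir(model, 90, n_taps = 16), "n_taps")
})

test_that("ECAP generator injects a piecewise-linear growth with hinge at threshold", {
  cfg <- ecap_sim_config(threshold_level = 100, growth_slope = 2,
                         noise_sd = 0, levels = c(80, 100, 120, 140))
  gf <- measure_growth(simulate_ecap_session(cfg))
  expect_equal(gf$points$p1n1_uv, c(0, 0, 40, 80))
  # level = threshold + 40 with slope 2: exactly 80 uV
  expect_equal(gf$points$p1n1_uv[4], 80)
  expect_error(ecap_sim_config(levels = numeric(0)), "non-empty")
  expect_error(ecap_sim_config(levels = c(120, 110)), "increasing")
  expect_error(ecap_sim_config(n1_latency_ms = 0.7, p1_latency_ms = 0.6),
               "precede")
})

test_that("every generator is a pure function of its configuration and seed", {
  c1 <- simulate_ecap_session(ecap_sim_config(seed = 7))
  c2 <- simulate_ecap_session(ecap_sim_config(seed = 7))
  expect_identical(c1, c2)
  l1 <- simulate_impedance_log(impedance_sim_config(seed = 5), 30)
  l2 <- simulate_impedance_log(impedance_sim_config(seed = 5), 30)
  expect_identical(l1, l2)
  t1 <- simulate_trajectory(trajectory_sim_config(seed = 3,
                                                  tracker_noise_deg = 1))
  t2 <- simulate_trajectory(trajectory_sim_config(seed = 3,
                                                  tracker_noise_deg = 1))
  expect_identical(t1, t2)
  # different seeds differ
  c3 <- simulate_ecap_session(ecap_sim_config(seed = 8))
  expect_false(identical(c1, c3))
})

test_that("impedance course runs baseline to plateau with planted failures", {
  cfg <- impedance_sim_config(noise_sd = 0, planted_failures = list(
    list(animal = "F1", ear = "left", electrode = "AE3", day = 43,
         type = "open")))
  log <- simulate_impedance_log(cfg, 200)
  expect_equal(unique(log$kohm[log$day == 0 & log$animal != "F1"]), 1.9)
  # terminal value within 1% of the plateau (sigmoid limit; AE4 offset -0.2)
  term <- log$kohm[log$day == 199 & log$electrode == "AE4" &
                     log$animal == "F2" & log$ear == "left" & log$mode == "CG"]
  expect_lt(abs(term - (8.5 - 0.2)) / 8.3, 0.01)
  # planted open: every reading from day 43 onward exceeds 20 kOhm
  ae3 <- log[log$animal == "F1" & log$ear == "left" & log$electrode == "AE3", ]
  expect_true(all(ae3$kohm[ae3$day >= 43] > 20))
  expect_true(all(ae3$kohm[ae3$day < 43] < 20))
  expect_error(impedance_sim_config(baseline_kohm = 9, plateau_kohm = 8),
               "baseline")
  expect_error(simulate_impedance_log(cfg, 0), "n_days")
})

test_that("trajectory generator reaches its bearing with a quiet pre-latency phase", {
  cfg <- trajectory_sim_config(latency_ms = 200, final_bearing_deg = 42,
                               tracker_noise_deg = 0)
  traj <- simulate_trajectory(cfg)
  ang <- angles_from_xy(traj)
  # asymptote: mean of last 3 frames equals the configured bearing
  expect_lt(abs(mean(utils::tail(ang, 3)) - 42), 0.1)
  # monotone after onset in the noiseless model
  expect_true(all(diff(ang[traj$onset_index:length(ang)]) >= -1e-9))
  # no movement before the scoring rule's first moving frame
  first_move <- traj$onset_index + round(0.2 * 60) - 2
  expect_true(all(abs(diff(ang[1:(first_move - 1)])) < 1))
  # zero bearing: no angles at all
  flat <- simulate_trajectory(trajectory_sim_config(final_bearing_deg = 0))
  expect_true(all(angles_from_xy(flat) == 0))
  expect_error(trajectory_sim_config(latency_ms = 1200), "latency_ms")
  expect_error(trajectory_sim_config(fps = 0), "fps")
})
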