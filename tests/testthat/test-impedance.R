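make_log <- function(kohm, electrode = "AE1", animal = "F1", ear = "left",
                     day = 0, mode = "CG") {
  data.frame(animal = animal, ear = ear, electrode = electrode,
             day = day, mode = mode, kohm = kohm)
}

test_that("classification partitions impedances at the 1 and 20 kOhm rules", {
  expect_equal(classify_impedance(0.5), "closed")
  expect_equal(classify_impedance(25), "open")
  expect_equal(classify_impedance(5), "functional")
  # boundaries are within the desired range (failure rules are strict)
  expect_equal(classify_impedance(c(1, 20)), c("functional", "functional"))
  expect_error(classify_impedance(0), "positive")
  # partition: every positive value maps to exactly one status
  withr::with_seed(41, {
    v <- exp(runif(200, log(0.1), log(40)))
    s <- classify_impedance(v)
    expect_true(all(s %in% c("closed", "open", "functional")))
    expect_equal(s == "functional", v >= 1 & v <= 20)
  })
})

test_that("epoch summaries use the sample sd and exclude failure codes", {
  log <- make_log(c(1, 2, 3), day = c(1, 2, 3))
  s <- epoch_summary(log, c(0, 4))
  expect_equal(s$mean_kohm, 2)
  expect_equal(s$sd_kohm, 1)
  expect_equal(s$n, 3)
  # single record: sd reported as 0 and flagged via n
  one <- epoch_summary(make_log(4.2), c(0, 0))
  expect_equal(one$sd_kohm, 0)
  expect_equal(one$n, 1)
  # an open reading inside the window is excluded, and counted
  mixed <- epoch_summary(make_log(c(2, 25), day = c(1, 1)), c(0, 4))
  expect_equal(mixed$mean_kohm, 2)
  expect_equal(mixed$n_excluded, 1)
  expect_error(epoch_summary(log, c(10, 20)), "no records")
})

test_that("noiseless generator epochs reproduce the configured course", {
  cfg <- impedance_sim_config(noise_sd = 0, position_offset_kohm = numeric(0))
  log <- simulate_impedance_log(cfg, 120)
  expect_equal(epoch_summary(log, c(0, 0), "CG")$mean_kohm, 1.9)
  late <- epoch_summary(log, c(100, 119), "CG")
  expect_equal(late$mean_kohm, 8.5, tolerance = 1e-6)
})

test_that("functional percentage counts positions whose every reading is in range", {
  # 32 positions, 2 always out of range: 93.75%
  grid <- expand.grid(animal = c("F1", "F2"), ear = c("left", "right"),
                      electrode = paste0("AE", 1:8), day = 0:9, mode = "CG",
                      stringsAsFactors = FALSE)
  grid$kohm <- 5
  bad <- grid$animal == "F1" & grid$ear == "left" &
    grid$electrode %in% c("AE1", "AE2") & grid$day >= 5
  grid$kohm[bad] <- 25
  pct <- functional_fraction(grid)
  expect_equal(as.numeric(pct), 100 * 30 / 32)
  expect_equal(attr(pct, "n_positions"), 32)
  # all functional
  grid$kohm <- 5
  expect_equal(as.numeric(functional_fraction(grid)), 100)
  # monotone non-increasing as failures are planted
  base_cfg <- function(failures) impedance_sim_config(
    planted_failures = failures, seed = 9)
  f1 <- list(list(animal = "F1", ear = "left", electrode = "AE1", day = 10,
                  type = "open"))
  f2 <- c(f1, list(list(animal = "F2", ear = "right", electrode = "AE5",
                        day = 20, type = "closed")))
  p0 <- functional_fraction(simulate_impedance_log(base_cfg(list()), 30))
  p1 <- functional_fraction(simulate_impedance_log(base_cfg(f1), 30))
  p2 <- functional_fraction(simulate_impedance_log(base_cfg(f2), 30))
  expect_true(as.numeric(p0) >= as.numeric(p1))
  expect_true(as.numeric(p1) > as.numeric(p2))
})

test_that("array profile preserves the position ordering and drops failures", {
  log <- make_log(rep(5, 7), electrode = paste0("AE", 1:7))
  prof <- per_position_profile(log)
  expect_equal(prof$mean_kohm, rep(5, 7))
  # synthetic profile: AE1 highest, AE5 lowest, ordering preserved
  cfg <- impedance_sim_config(noise_sd = 0)
  log2 <- simulate_impedance_log(cfg, 60)
  prof2 <- per_position_profile(log2[log2$day >= 30, ])
  expect_equal(prof2$electrode[which.max(prof2$mean_kohm)], "AE1")
  expect_equal(prof2$electrode[which.min(prof2$mean_kohm)], "AE5")
  # one open value is excluded from its position's mean
  log3 <- make_log(c(5, 5, 25), electrode = "AE1", day = c(0, 1, 2))
  prof3 <- per_position_profile(log3)
  expect_equal(prof3$mean_kohm, 5)
  expect_equal(prof3$n, 2)
  # a position with no usable data is absent, not zero
  log4 <- rbind(make_log(5, electrode = "AE1"),
                make_log(25, electrode = "AE2"))
  expect_equal(per_position_profile(log4)$electrode, "AE1")
})
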