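make_frames <- function(probe, mp, ma, ns, fs = 40000, level = 120) {
  ecap_frame_set(probe, mp, ma, ns, fs, level)
}

test_that("forward-masking arithmetic cancels shared additive artifacts", {
  t <- (0:79) / 40
  artifact <- 500 * exp(-3 * t)
  masker_art <- 300 * exp(-3 * (t + 0.5))
  # pure artifact, zero neural response: residual below 1e-9 of artifact
  f <- make_frames(artifact, masker_art + artifact, masker_art, numeric(80))
  expect_lt(max(abs(cancel_artifact(f)$samples)), 1e-9 * 500)
  # neural template added to probe-alone only: recovered exactly
  neural <- -50 * exp(-(t - 0.3)^2 / 0.01) + 30 * exp(-(t - 0.6)^2 / 0.02)
  f2 <- make_frames(artifact + neural, masker_art + artifact, masker_art,
                    numeric(80))
  expect_equal(cancel_artifact(f2)$samples, neural)
  # baseline offset in the no-stimulus frame is subtracted too
  f3 <- make_frames(artifact + neural + 7, masker_art + artifact + 7,
                    masker_art + 7, rep(7, 80))
  expect_equal(cancel_artifact(f3)$samples, neural)
  expect_error(ecap_frame_set(numeric(10), numeric(10), numeric(10),
                              numeric(9), 40000, 120), "equal lengths")
})

test_that("cancellation is exact for any shared artifact (property)", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- 80
      art_p <- rnorm(n, sd = 100)
      art_m <- rnorm(n, sd = 100)
      base <- rnorm(n, sd = 5)
      neural <- rnorm(n, sd = 20)
      f <- make_frames(art_p + base + neural, art_m + art_p + base,
                       art_m + base, base)
      expect_lt(max(abs(cancel_artifact(f)$samples - neural)), 1e-9)
    }
  })
})

test_that("P1-N1 amplitude is the windowed peak-to-trough, clipped at zero", {
  fs <- 40000
  t <- (0:79) / 40
  w <- structure(list(samples = numeric(80), fs = fs), class = "ecap_waveform")
  expect_equal(measure_p1n1(w), 0)
  w$samples <- -50 * exp(-(t - 0.3)^2 / 0.005) + 30 * exp(-(t - 0.6)^2 / 0.01)
  amp <- measure_p1n1(w)
  expect_equal(amp, max(w$samples[t >= 0.4 & t <= 1]) -
                 min(w$samples[t >= 0.1 & t <= 0.5]))
  expect_gt(amp, 79)  # trough -50, peak +30
  w2 <- w; w2$samples <- 2 * w$samples
  expect_equal(measure_p1n1(w2), 2 * amp)  # linearity
  expect_error(measure_p1n1(w, n1_window = c(0.1, 0.5), p1_window = c(1.5, 3)),
               "outside")
  expect_error(measure_p1n1(w, n1_window = c(0.6, 0.9), p1_window = c(0.4, 1)),
               "precede")
})

test_that("threshold extrapolation matches the closed-form least squares", {
  # collinear: slope 2, zero crossing at level 100
  gf <- growth_function(c(120, 140, 160), c(40, 80, 120))
  est <- fit_threshold(gf)
  expect_equal(est$slope, 2)
  expect_equal(est$threshold, 100)
  expect_equal(est$n_used, 3)
  expect_equal(est$excluded, 0)
  # a 25 uV point sits under the 30 uV noise floor: excluded, fit unchanged
  gf2 <- growth_function(c(100, 120, 140, 160), c(25, 40, 80, 120))
  est2 <- fit_threshold(gf2)
  expect_equal(est2$threshold, 100)
  expect_equal(est2$excluded, 1)
  # a point exactly at the floor is retained (strict < exclusion)
  gf3 <- growth_function(c(115, 140, 160), c(30, 80, 120))
  expect_equal(fit_threshold(gf3)$n_used, 3)
})

test_that("threshold contracts: insufficient data and non-growing functions", {
  expect_error(fit_threshold(growth_function(c(100, 120), c(10, 25))),
               "insufficient")
  expect_error(fit_threshold(growth_function(c(120, 140), c(40, 40))),
               "non-growing")
  expect_error(growth_function(c(120, 120), c(40, 50)), "duplicate")
  expect_error(growth_function(c(120, 140), c(-1, 50)), ">= 0")
})

test_that("noiseless synthetic sessions recover the configured threshold exactly", {
  for (thr in c(90, 100, 117.5)) {
    cfg <- ecap_sim_config(threshold_level = thr, noise_sd = 0,
                           levels = seq(thr + 20, thr + 60, by = 10))
    est <- fit_threshold(measure_growth(simulate_ecap_session(cfg)))
    expect_lt(abs(est$threshold - thr), 1e-6)
    expect_lt(abs(est$slope - 2), 1e-9)
  }
})

test_that("raising all amplitudes by a constant lowers the threshold", {
  gf_lo <- growth_function(c(120, 140, 160), c(40, 80, 120))
  gf_hi <- growth_function(c(120, 140, 160), c(60, 100, 140))
  expect_lt(fit_threshold(gf_hi)$threshold, fit_threshold(gf_lo)$threshold)
})

test_that("threshold stability reproduces exact slopes and the t-test", {
  # constant thresholds: every slope zero, degenerate t
  flat <- expand.grid(electrode = c("AE1", "AE2", "AE3"), day = c(0, 7, 14))
  flat$threshold <- 100
  st <- threshold_stability(flat)
  expect_equal(unname(st$slopes), c(0, 0, 0))
  expect_equal(st$mean_slope, 0)
  expect_equal(st$p_value, 1)
  # exact rise of 0.5 units/day
  rise <- expand.grid(electrode = c("AE1", "AE2"), day = c(0, 10, 20))
  rise$threshold <- 100 + 0.5 * rise$day
  expect_equal(unname(threshold_stability(rise)$slopes), c(0.5, 0.5))
  # slopes -1, 0, +1: mean 0, t = 0, p = 1 (hand-computed one-sample t)
  mixed <- expand.grid(electrode = c("AE1", "AE2", "AE3"), day = c(0, 10))
  mixed$threshold <- 100 + c(-1, 0, 1)[match(mixed$electrode,
                                             c("AE1", "AE2", "AE3"))] * mixed$day
  st3 <- threshold_stability(mixed)
  expect_equal(st3$mean_slope, 0)
  expect_equal(st3$t_statistic, 0)
  expect_equal(st3$p_value, 1)
  expect_error(threshold_stability(data.frame(electrode = "AE1", day = 1,
                                              threshold = 100)),
               "fewer than 2")
})
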