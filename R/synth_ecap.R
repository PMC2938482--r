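# Synthetic ECAP sessions: four forward-masking frames per stimulus level,
# with an exponentially decaying stimulus artifact, a biphasic neural template
# whose P1-N1 span grows linearly above threshold, and Gaussian noise.

#' Configuration for a synthetic ECAP recording session
#'
#' The neural response obeys a hinged-linear amplitude growth model:
#' P1-N1 amplitude = `max(0, growth_slope * (level - threshold_level))`.
#' Stimulus levels are abstract device units; only differences matter.
#'
#' @param threshold_level level at which the neural response first appears.
#' @param growth_slope uV of P1-N1 growth per level unit (>= 0).
#' @param artifact_amplitude initial stimulus-artifact amplitude, uV.
#' @param artifact_decay artifact decay rate, 1/ms.
#' @param noise_sd per-sweep recording noise standard deviation, uV. Each
#'   stored frame is the average of `n_sweeps` stimulus repetitions, so its
#'   residual noise sd is `noise_sd / sqrt(n_sweeps)`.
#' @param n_sweeps stimulus repetitions averaged into each stored frame.
#' @param levels strictly increasing stimulus levels to record at.
#' @param n1_latency_ms,p1_latency_ms latencies of the negative trough and the
#'   later positive peak of the neural template (N1 before P1).
#' @param fs recording sample rate, Hz.
#' @param duration_ms length of each post-stimulus trace, ms.
#' @param seed integer RNG seed.
#' @param electrode,ear,day metadata carried on each frame set.
#' @return object of class `ecap_sim_config`.
#' @export
ecap_sim_config <- function(threshold_level = 100,
                            growth_slope = 2,
                            artifact_amplitude = 500,
                            artifact_decay = 3,
                            noise_sd = 10,
                            n_sweeps = 500,
                            levels = seq(110, 160, by = 10),
                            n1_latency_ms = 0.3,
                            p1_latency_ms = 0.6,
                            fs = 40000,
                            duration_ms = 2,
                            seed = 1,
                            electrode = "AE1", ear = "left", day = 14) {
  if (growth_slope < 0) stop("growth_slope must be >= 0")
  if (length(levels) == 0) stop("levels must be non-empty")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (!(n1_latency_ms < p1_latency_ms)) stop("n1_latency_ms must precede p1_latency_ms")
  structure(as.list(environment()), class = "ecap_sim_config")
}

#' Container for the four forward-masking frames at one stimulus level
#'
#' @param probe_alone,masker_probe,masker_alone,no_stimulus voltage traces
#'   (uV) on a shared post-stimulus time base, equal lengths.
#' @param fs sample rate, Hz.
#' @param stimulus_level stimulus level of the probe.
#' @param electrode,ear,day metadata.
#' @return object of class `ecap_frame_set`.
#' @export
ecap_frame_set <- function(probe_alone, masker_probe, masker_alone,
                           no_stimulus, fs, stimulus_level,
                           electrode = NA_character_, ear = NA_character_,
                           day = NA_real_) {
  n <- length(probe_alone)
  if (length(masker_probe) != n || length(masker_alone) != n ||
      length(no_stimulus) != n) {
    stop("the four frames must have equal lengths")
  }
  if (fs <= 0) stop("fs must be > 0")
  structure(
    list(probe_alone = probe_alone, masker_probe = masker_probe,
         masker_alone = masker_alone, no_stimulus = no_stimulus,
         fs = fs, stimulus_level = stimulus_level,
         electrode = electrode, ear = ear, day = day),
    class = "ecap_frame_set"
  )
}

# Biphasic neural template on time grid t_ms, normalized so that
# max(over P1 window) - min(over N1 window) == 1 on that grid.
ecap_template <- function(t_ms, n1_latency_ms, p1_latency_ms) {
  sd_n <- 0.08
  sd_p <- 0.15
  u <- -exp(-(t_ms - n1_latency_ms)^2 / (2 * sd_n^2)) +
    0.6 * exp(-(t_ms - p1_latency_ms)^2 / (2 * sd_p^2))
  span <- max(u) - min(u)
  u / span
}

#' Simulate a forward-masking ECAP session
#'
#' Produces one [ecap_frame_set()] per stimulus level. The probe-alone frame
#' contains the probe artifact plus a neural response whose P1-N1 span equals
#' `max(0, growth_slope * (level - threshold_level))`; the masker+probe and
#' masker-alone frames differ by the probe artifact only (complete masking of
#' the probe response); the no-stimulus frame is recording noise alone. Each
#' frame carries independent Gaussian noise with the residual sd of an
#' `n_sweeps`-average, `noise_sd / sqrt(n_sweeps)`. Output is a pure function
#' of the configuration (including its seed).
#'
#' @param cfg an [ecap_sim_config()].
#' @return list of `ecap_frame_set`, one per level.
#' @export
simulate_ecap_session <- function(cfg) {
  stopifnot(inherits(cfg, "ecap_sim_config"))
  n <- round(cfg$duration_ms * cfg$fs / 1000)
  t_ms <- (seq_len(n) - 1) / cfg$fs * 1000
  template <- ecap_template(t_ms, cfg$n1_latency_ms, cfg$p1_latency_ms)
  art_probe <- cfg$artifact_amplitude * exp(-cfg$artifact_decay * t_ms)
  # masker artifact: same decay, partially decayed tail of the earlier pulse
  art_masker <- 0.6 * cfg$artifact_amplitude *
    exp(-cfg$artifact_decay * (t_ms + 0.5))
  with_fixed_seed(cfg$seed, {
    lapply(cfg$levels, function(level) {
      amp <- max(0, cfg$growth_slope * (level - cfg$threshold_level))
      neural <- amp * template
      frame_sd <- cfg$noise_sd / sqrt(cfg$n_sweeps)
      noise <- function() stats::rnorm(n, sd = frame_sd)
      ecap_frame_set(
        probe_alone = art_probe + neural + noise(),
        masker_probe = art_masker + art_probe + noise(),
        masker_alone = art_masker + noise(),
        no_stimulus = noise(),
        fs = cfg$fs, stimulus_level = level,
        electrode = cfg$electrode, ear = cfg$ear, day = cfg$day
      )
    })
  })
}
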