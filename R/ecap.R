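# ECAP analysis: forward-masking artifact cancellation, P1-N1 amplitude,
# amplitude-growth-function threshold extrapolation with a noise-floor rule,
# and longitudinal threshold-stability testing.

#' Cancel stimulus artifact by forward-masking frame arithmetic
#'
#' Combines the four recorded frames as
#' `probe_alone - (masker_probe - masker_alone) - no_stimulus`. When the probe
#' artifact is additive and identical across frames and the masker completely
#' suppresses the probe-evoked response in the masker+probe frame, the
#' artifact terms cancel algebraically and the result is the probe-evoked
#' neural response alone.
#'
#' @param frames an [ecap_frame_set()].
#' @return object of class `ecap_waveform` (`samples` in uV, `fs`, metadata).
#' @export
cancel_artifact <- function(frames) {
  stopifnot(inherits(frames, "ecap_frame_set"))
  w <- frames$probe_alone - (frames$masker_probe - frames$masker_alone) -
    frames$no_stimulus
  structure(list(samples = w, fs = frames$fs,
                 stimulus_level = frames$stimulus_level,
                 electrode = frames$electrode, ear = frames$ear,
                 day = frames$day),
            class = "ecap_waveform")
}

#' P1-N1 amplitude of an ECAP waveform
#'
#' Amplitude is the maximum over the P1 window minus the minimum over the N1
#' window (N1, the early negative trough, precedes P1 here), clipped at zero.
#'
#' @param w an `ecap_waveform` from [cancel_artifact()].
#' @param n1_window,p1_window length-2 numeric, ms after probe onset; the N1
#'   window must start before the P1 window and both must lie inside the
#'   trace.
#' @return P1-N1 amplitude in uV (>= 0).
#' @export
measure_p1n1 <- function(w, n1_window = c(0.1, 0.5), p1_window = c(0.4, 1.0)) {
  stopifnot(inherits(w, "ecap_waveform"))
  if (n1_window[1] >= p1_window[1]) stop("n1_window must precede p1_window")
  dur_ms <- length(w$samples) / w$fs * 1000
  win_idx <- function(win) {
    if (win[1] < 0 || win[2] > dur_ms || win[1] >= win[2]) {
      stop("window [", win[1], ", ", win[2], "] ms outside the trace")
    }
    i0 <- max(1, floor(win[1] * w$fs / 1000) + 1)
    i1 <- min(length(w$samples), ceiling(win[2] * w$fs / 1000))
    i0:i1
  }
  n1 <- min(w$samples[win_idx(n1_window)])
  p1 <- max(w$samples[win_idx(p1_window)])
  max(p1 - n1, 0)
}

#' Build an amplitude growth function from a recorded session
#'
#' Cancels the artifact and measures P1-N1 at every stimulus level.
#'
#' @param session list of [ecap_frame_set()] (e.g. from
#'   [simulate_ecap_session()]).
#' @param n1_window,p1_window see [measure_p1n1()].
#' @return object of class `growth_function`: data.frame `points`
#'   (`level`, `p1n1_uv`) plus electrode/ear/day metadata.
#' @export
measure_growth <- function(session, n1_window = c(0.1, 0.5),
                           p1_window = c(0.4, 1.0)) {
  if (length(session) == 0) stop("empty session")
  levels <- vapply(session, function(f) f$stimulus_level, numeric(1))
  if (anyDuplicated(levels)) stop("duplicate stimulus levels")
  amps <- vapply(session, function(f) {
    measure_p1n1(cancel_artifact(f), n1_window, p1_window)
  }, numeric(1))
  growth_function(levels, amps,
                  electrode = session[[1]]$electrode,
                  ear = session[[1]]$ear, day = session[[1]]$day)
}

#' Construct a growth function from levels and amplitudes
#' @param levels unique stimulus levels.
#' @param p1n1_uv non-negative P1-N1 amplitudes, uV.
#' @param electrode,ear,day metadata.
#' @return object of class `growth_function`.
#' @export
growth_function <- function(levels, p1n1_uv, electrode = NA_character_,
                            ear = NA_character_, day = NA_real_) {
  if (length(levels) != length(p1n1_uv)) stop("levels and amplitudes differ in length")
  if (anyDuplicated(levels)) stop("duplicate stimulus levels")
  if (any(p1n1_uv < 0)) stop("amplitudes must be >= 0")
  structure(list(points = data.frame(level = levels, p1n1_uv = p1n1_uv),
                 electrode = electrode, ear = ear, day = day),
            class = "growth_function")
}

#' ECAP threshold by linear extrapolation of the growth function
#'
#' Points with P1-N1 amplitude strictly below the noise floor are considered
#' noise and excluded; an ordinary least-squares line is fitted through the
#' retained points and the threshold is its zero crossing,
#' `-intercept / slope`.
#'
#' @param gf a [growth_function()].
#' @param noise_floor_uv amplitudes below this are excluded (default 30 uV).
#' @return object of class `threshold_estimate`: `threshold`, `slope`
#'   (uV per level unit), `intercept`, `n_used`, `excluded`.
#' @export
fit_threshold <- function(gf, noise_floor_uv = 30) {
  stopifnot(inherits(gf, "growth_function"))
  pts <- gf$points
  keep <- pts$p1n1_uv >= noise_floor_uv
  n_used <- sum(keep)
  if (n_used < 2) {
    stop("insufficient data: fewer than 2 points at or above the ",
         noise_floor_uv, " uV noise floor")
  }
  fit <- stats::lm(p1n1_uv ~ level, data = pts[keep, ])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 1e-9 * max(pts$p1n1_uv[keep])) {
    stop("non-growing function: fitted slope is not positive")
  }
  structure(list(threshold = -intercept / slope, slope = slope,
                 intercept = intercept, n_used = n_used,
                 excluded = sum(!keep),
                 electrode = gf$electrode, ear = gf$ear, day = gf$day),
            class = "threshold_estimate")
}

#' Longitudinal ECAP threshold stability
#'
#' Fits an ordinary least-squares regression of threshold against
#' post-operative day for every electrode position (pooling ears), then tests
#' the per-electrode slopes against zero with a two-sided one-sample t-test.
#' A non-significant result indicates thresholds that remain constant over
#' the monitoring period.
#'
#' @param series data.frame with columns `electrode`, `day`, `threshold`
#'   (optionally `ear`, pooled).
#' @return list: `slopes` (named, level units/day), `mean_slope`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
threshold_stability <- function(series) {
  stopifnot(all(c("electrode", "day", "threshold") %in% names(series)))
  if (any(series$day < 0)) stop("days must be non-negative")
  electrodes <- sort(unique(series$electrode))
  slopes <- vapply(electrodes, function(e) {
    d <- series[series$electrode == e, ]
    if (length(unique(d$day)) < 2) {
      stop("electrode ", e, " has fewer than 2 distinct days")
    }
    unname(stats::coef(stats::lm(threshold ~ day, data = d))[2])
  }, numeric(1))
  names(slopes) <- electrodes
  if (length(slopes) < 2) stop("need >= 2 electrodes for the t-test")
  scale <- max(abs(slopes), 1)
  if (stats::sd(slopes) < 1e-10 * scale) {
    # degenerate: (numerically) identical slopes; the t statistic is undefined
    zero <- abs(mean(slopes)) < 1e-10 * scale
    return(list(slopes = slopes, mean_slope = mean(slopes),
                t_statistic = NA_real_, df = length(slopes) - 1,
                p_value = if (zero) 1 else 0))
  }
  tt <- stats::t.test(slopes, mu = 0)
  list(slopes = slopes, mean_slope = mean(slopes),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
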