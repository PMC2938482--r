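# Synthetic binaural acoustics: a spherical-head (Woodworth) delay model with
# a first-order frequency-dependent shadow gain, rendered as left/right
# impulse responses at a shared sample rate.

#' Spherical-head model for synthetic binaural impulse responses
#'
#' Parameterizes the generator that stands in for free-field recordings from a
#' small-headed mammal on a loudspeaker hoop. The effective radius and shadow
#' strengths are calibrations chosen to land in the cue ranges typical of a
#' ferret-sized head (ITD half-range roughly 165-255 us); they are arbitrary
#' generator settings, not species constants. The `jacket_pocket` site defaults
#' to a slightly smaller radius and weaker shadow, reflecting microphones worn
#' in a jacket at the neckline rather than in the ear canals.
#'
#' @param effective_radius acoustic head radius in metres.
#' @param speed_of_sound in m/s.
#' @param mic_site `"ear_canal"` or `"jacket_pocket"`.
#' @param shadow_low_db,shadow_high_db head-shadow ILD half-range (dB) in the
#'   low (<= 2 kHz) and high (>= 3.5 kHz) frequency regions; the per-band ILD
#'   at source angle theta is `shadow * sin(theta)` dB, larger at high
#'   frequencies as head shadowing dictates.
#' @param head_orientation rotation of the head frame relative to the chamber
#'   frame, degrees; cues depend on `source_angle - head_orientation`.
#' @return object of class `head_model`.
#' @export
head_model <- function(effective_radius = NULL,
                       speed_of_sound = 343,
                       mic_site = c("ear_canal", "jacket_pocket"),
                       shadow_low_db = NULL,
                       shadow_high_db = NULL,
                       head_orientation = 0) {
  mic_site <- match.arg(mic_site)
  defaults <- if (mic_site == "ear_canal") {
    list(radius = 0.0253, low = 4.3, high = 10.9)
  } else {
    list(radius = 0.0225, low = 4.2, high = 9.8)
  }
  if (is.null(effective_radius)) effective_radius <- defaults$radius
  if (is.null(shadow_low_db)) shadow_low_db <- defaults$low
  if (is.null(shadow_high_db)) shadow_high_db <- defaults$high
  if (effective_radius <= 0) stop("effective_radius must be > 0")
  if (speed_of_sound <= 0) stop("speed_of_sound must be > 0")
  structure(
    list(effective_radius = effective_radius,
         speed_of_sound = speed_of_sound,
         mic_site = mic_site,
         shadow_low_db = shadow_low_db,
         shadow_high_db = shadow_high_db,
         head_orientation = head_orientation),
    class = "head_model"
  )
}

#' Woodworth interaural time difference
#'
#' Frequency-independent spherical-head ITD: `(a/c) * (sin(theta) + theta)`
#' for `|theta| <= 90` degrees (theta in radians inside the formula), mirrored
#' about 90 degrees for rear angles so the function is continuous and odd.
#' Positive ITD means the right ear leads (source on the right).
#'
#' @param angle_deg source angle(s) in degrees, negative = left.
#' @param radius head radius in metres.
#' @param speed_of_sound m/s.
#' @return ITD in seconds (same sign convention as the angle).
#' @export
woodworth_itd <- function(angle_deg, radius, speed_of_sound = 343) {
  th <- wrap_angle(angle_deg)
  s <- sign(th)
  a <- abs(th)
  eff <- ifelse(a <= 90, a, 180 - a)
  rad <- eff * pi / 180
  s * (radius / speed_of_sound) * (sin(rad) + rad)
}

#' Container for a left/right impulse-response pair
#'
#' @param left_ir,right_ir numeric sample vectors of equal length.
#' @param fs sample rate, Hz.
#' @param source_angle degrees (negative = left).
#' @param mic_site `"ear_canal"` or `"jacket_pocket"`.
#' @return object of class `impulse_response_pair`.
#' @export
impulse_response_pair <- function(left_ir, right_ir, fs,
                                  source_angle = NA_real_,
                                  mic_site = "ear_canal") {
  if (length(left_ir) != length(right_ir)) stop("channel lengths differ")
  if (!all(is.finite(left_ir)) || !all(is.finite(right_ir))) {
    stop("impulse responses must be finite")
  }
  if (fs <= 0) stop("fs must be > 0")
  structure(
    list(left_ir = as.numeric(left_ir), right_ir = as.numeric(right_ir),
         fs = fs, source_angle = source_angle, mic_site = mic_site),
    class = "impulse_response_pair"
  )
}

# Windowed-sinc fractional-delay kernel of length n centred near delay d
# (samples). Band-limited interpolation keeps sub-sample delays representable.
frac_delay_kernel <- function(n, d) {
  k <- seq_len(n) - 1
  x <- k - d
  h <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  # Blackman window centred on the delay to confine the kernel support
  m <- (n - 1) / 2
  w <- 0.42 - 0.5 * cos(2 * pi * (k - d + m) / (n - 1)) +
    0.08 * cos(4 * pi * (k - d + m) / (n - 1))
  w[abs(k - d) > m] <- 0
  h * pmax(w, 0)
}

# Frequency-dependent shadow gain (dB) at frequency f: flat at shadow_low
# below 2 kHz, flat at shadow_high above 3.5 kHz, log-linear in between.
# Both default analysis bands (0.75-1.5 and 4-8 kHz) sit in the flat regions,
# so in-band ILDs equal the configured values exactly.
shadow_gain_db <- function(f, shadow_low_db, shadow_high_db,
                           f_lo = 2000, f_hi = 3500) {
  g <- numeric(length(f))
  g[f <= f_lo] <- shadow_low_db
  g[f >= f_hi] <- shadow_high_db
  mid <- f > f_lo & f < f_hi
  if (any(mid)) {
    t <- (log(f[mid]) - log(f_lo)) / (log(f_hi) - log(f_lo))
    g[mid] <- shadow_low_db + t * (shadow_high_db - shadow_low_db)
  }
  g
}

# Apply a zero-phase gain profile (dB, defined on 0..fs/2) to a real signal.
apply_zero_phase_gain <- function(x, fs, gain_db_fun) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f_folded <- pmin(f, fs - f)
  g <- 10^(gain_db_fun(f_folded) / 20)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

#' Simulate a binaural impulse-response pair for one source angle
#'
#' Renders left and right impulse responses whose relative delay equals the
#' Woodworth ITD of the source angle in the head frame
#' (`source_angle - head_orientation`) and whose per-band level difference
#' follows the head-shadow model: ILD(f, theta) = shadow(f) * sin(theta) dB,
#' split symmetrically between the two ears. Fractional-sample delays are
#' realized by windowed-sinc interpolation; the shadow gain is applied with
#' zero phase so it cannot bias the delay. Deterministic (no noise).
#'
#' @param model a [head_model()].
#' @param source_angle degrees in the chamber frame, `|angle| <= 180`.
#' @param fs sample rate, Hz (default 80 kHz).
#' @param n_taps impulse-response length in samples; must comfortably contain
#'   the maximum interaural delay.
#' @return an [impulse_response_pair()].
#' @export
simulate_head_ir <- function(model, source_angle, fs = 80000, n_taps = 512) {
  stopifnot(inherits(model, "head_model"))
  if (fs <= 0) stop("fs must be > 0")
  if (abs(source_angle) > 180) stop("|source_angle| must be <= 180 degrees")
  theta <- wrap_angle(source_angle - model$head_orientation)
  itd_s <- woodworth_itd(theta, model$effective_radius, model$speed_of_sound)
  itd_samples <- itd_s * fs
  centre <- n_taps / 2
  max_half <- (model$effective_radius / model$speed_of_sound) *
    (1 + pi / 2) * fs / 2
  if (n_taps < 2 * (max_half + 32)) {
    stop("n_taps too small to contain the maximum interaural delay")
  }
  # positive ITD: right ear leads, left ear lags
  h_left <- frac_delay_kernel(n_taps, centre + itd_samples / 2)
  h_right <- frac_delay_kernel(n_taps, centre - itd_samples / 2)
  sin_t <- sin(theta * pi / 180)
  gain_fun <- function(f) {
    shadow_gain_db(f, model$shadow_low_db, model$shadow_high_db) * sin_t
  }
  h_left <- apply_zero_phase_gain(h_left, fs, function(f) -gain_fun(f) / 2)
  h_right <- apply_zero_phase_gain(h_right, fs, function(f) gain_fun(f) / 2)
  impulse_response_pair(h_left, h_right, fs,
                        source_angle = source_angle, mic_site = model$mic_site)
}
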