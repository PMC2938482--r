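# Acoustic measurement chain: complementary Golay codes, impulse-response
# estimation by Golay deconvolution, ITD by cross-correlation with parabolic
# peak interpolation, ILD by band-limited RMS, cue curves versus azimuth and
# their zero-crossing (F0) alignment.

#' Generate a complementary Golay code pair
#'
#' Standard append/negate recursion: starting from `a = b = (+1)`, each step
#' maps `(a, b)` to `(ab, a(-b))`. The pair of length `2^order` satisfies the
#' defining property that the two autocorrelations sum to `2 * 2^order` at lag
#' zero and exactly zero at every other lag, which is what makes exact
#' impulse-response recovery possible.
#'
#' @param order non-negative integer; code length is `2^order` (order 9 gives
#'   the 512-point pair used for transfer-function measurement).
#' @return object of class `golay_pair` with elements `a`, `b`, `length`.
#' @export
generate_golay_pair <- function(order) {
  if (order < 0 || order != round(order)) stop("order must be a non-negative integer")
  a <- 1
  b <- 1
  for (i in seq_len(order)) {
    a_new <- c(a, b)
    b_new <- c(a, -b)
    a <- a_new
    b <- b_new
  }
  structure(list(a = a, b = b, length = 2^order), class = "golay_pair")
}

#' Container for a stereo recording of a known stimulus
#'
#' @param left,right sample vectors of equal length (arbitrary amplitude units).
#' @param fs sample rate, Hz.
#' @param source_angle degrees (negative = left).
#' @param mic_site `"ear_canal"` or `"jacket_pocket"`.
#' @return object of class `binaural_recording`.
#' @export
binaural_recording <- function(left, right, fs, source_angle = NA_real_,
                               mic_site = "ear_canal") {
  if (length(left) != length(right)) stop("channel lengths differ")
  if (fs <= 0) stop("fs must be > 0")
  structure(list(left = as.numeric(left), right = as.numeric(right), fs = fs,
                 source_angle = source_angle, mic_site = mic_site),
            class = "binaural_recording")
}

#' Record a Golay pair through a binaural impulse response
#'
#' Convenience wrapper for synthetic measurements: convolves each code with
#' each channel of `ir`, producing the two recordings that
#' [estimate_impulse_response()] expects.
#'
#' @param pair a [generate_golay_pair()].
#' @param ir an [impulse_response_pair()].
#' @return list with `resp_a`, `resp_b` (both [binaural_recording()]).
#' @export
record_golay <- function(pair, ir) {
  stopifnot(inherits(pair, "golay_pair"), inherits(ir, "impulse_response_pair"))
  mk <- function(code) {
    binaural_recording(convolve_full(code, ir$left_ir),
                       convolve_full(code, ir$right_ir),
                       ir$fs, ir$source_angle, ir$mic_site)
  }
  list(resp_a = mk(pair$a), resp_b = mk(pair$b))
}

#' Estimate a binaural impulse response by Golay deconvolution
#'
#' Per channel, `IR = (xcorr(resp_a, code_a) + xcorr(resp_b, code_b)) /
#' (2 * length)`. Because the codes' autocorrelations sum to a discrete delta,
#' this equals the true impulse response exactly for a noiseless linear
#' system.
#'
#' @param resp_a,resp_b [binaural_recording()]s of code A and code B through
#'   the same system; must share fs, angle and site, and be at least as long
#'   as the code.
#' @param pair the [generate_golay_pair()] that was played.
#' @return an [impulse_response_pair()].
#' @export
estimate_impulse_response <- function(resp_a, resp_b, pair) {
  stopifnot(inherits(resp_a, "binaural_recording"),
            inherits(resp_b, "binaural_recording"),
            inherits(pair, "golay_pair"))
  if (resp_a$fs != resp_b$fs) stop("recordings have mismatched sample rates")
  if (!identical(resp_a$mic_site, resp_b$mic_site) ||
      !identical(resp_a$source_angle, resp_b$source_angle)) {
    stop("recordings have mismatched metadata (site or angle)")
  }
  if (length(resp_a$left) < pair$length || length(resp_b$left) < pair$length) {
    stop("recordings shorter than the Golay code")
  }
  deconv <- function(xa, xb) {
    (cross_correlate_valid(xa, pair$a) + cross_correlate_valid(xb, pair$b)) /
      (2 * pair$length)
  }
  impulse_response_pair(deconv(resp_a$left, resp_b$left),
                        deconv(resp_a$right, resp_b$right),
                        resp_a$fs, resp_a$source_angle, resp_a$mic_site)
}

#' Interaural time difference by cross-correlation
#'
#' Finds the lag of the left channel relative to the right maximizing their
#' cross-correlation within `max_lag_us`, then refines the peak by 3-point
#' parabolic interpolation for sub-sample resolution. Positive ITD means the
#' right ear leads (left channel delayed; source on the right). Integer-lag
#' ties are broken toward the smaller absolute lag.
#'
#' @param ir an [impulse_response_pair()] (or any object with `left_ir`,
#'   `right_ir`, `fs`).
#' @param max_lag_us search half-width in microseconds; at least one sample
#'   period and less than the trace duration.
#' @return ITD in microseconds.
#' @export
compute_itd <- function(ir, max_lag_us = 1000) {
  left <- ir$left_ir
  right <- ir$right_ir
  fs <- ir$fs
  if (all(left == 0) || all(right == 0)) stop("silent (all-zero) channel")
  max_lag <- floor(max_lag_us * fs / 1e6)
  if (max_lag < 1) stop("max_lag_us smaller than one sample period")
  n <- length(left)
  if (max_lag >= n) stop("max_lag_us exceeds the impulse-response length")
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      sum(left[(1 + k):n] * right[1:(n - k)])
    } else {
      sum(left[1:(n + k)] * right[(1 - k):n])
    }
  }, numeric(1))
  # maximum, ties toward smaller |lag|
  ord <- order(abs(lags), lags)
  best <- ord[which.max(r[ord])]
  k <- lags[best]
  delta <- 0
  if (best > 1 && best < length(lags)) {
    denom <- r[best - 1] - 2 * r[best] + r[best + 1]
    if (denom < 0) delta <- 0.5 * (r[best - 1] - r[best + 1]) / denom
  }
  (k + delta) / fs * 1e6
}

#' Interaural level difference by band-limited RMS
#'
#' Band-pass filters both channels with a zero-phase (forward-backward)
#' 4th-order Butterworth filter, then returns
#' `20 * log10(RMS_right / RMS_left)` dB. Positive ILD means the source is on
#' the right (right ear louder). The band `(0, fs/2)` means unfiltered.
#'
#' @param ir an [impulse_response_pair()].
#' @param band numeric length-2, `(low, high)` in Hz with
#'   `0 <= low < high <= fs/2`; `c(0, fs/2)` skips filtering.
#' @return ILD in dB.
#' @export
compute_ild <- function(ir, band = c(0, ir$fs / 2)) {
  fs <- ir$fs
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1] || band[2] > fs / 2) {
    stop("band must satisfy 0 <= low < high <= fs/2")
  }
  left <- ir$left_ir
  right <- ir$right_ir
  if (!(band[1] == 0 && band[2] == fs / 2)) {
    if (band[1] == 0) stop("low edge must be > 0 for a band-pass filter")
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    left <- signal::filtfilt(bf, left)
    right <- signal::filtfilt(bf, right)
  }
  rl <- rms(left)
  rr <- rms(right)
  if (rl == 0 || rr == 0) stop("zero RMS in a channel within the requested band")
  20 * log10(rr / rl)
}

#' Assemble a cue curve across source angles
#'
#' Evaluates ITD and per-band ILD for one impulse response per angle and
#' returns them sorted by angle.
#'
#' @param irs list of [impulse_response_pair()], one per unique angle.
#' @param bands list of length-2 numeric vectors (Hz); defaults to the
#'   0.75-1.5 kHz and 4-8 kHz analysis bands.
#' @param max_lag_us ITD search half-width, microseconds.
#' @return object of class `cue_curve`: `angles` (degrees, increasing),
#'   `itd_us`, `ild_db` (matrix, angles x bands), `bands`, `mic_site`.
#' @export
build_cue_curve <- function(irs, bands = list(c(750, 1500), c(4000, 8000)),
                            max_lag_us = 1000) {
  if (length(irs) == 0) stop("no impulse responses supplied")
  angles <- vapply(irs, function(ir) ir$source_angle, numeric(1))
  if (anyDuplicated(angles)) stop("duplicate source angles")
  ord <- order(angles)
  irs <- irs[ord]
  angles <- angles[ord]
  itd <- vapply(irs, compute_itd, numeric(1), max_lag_us = max_lag_us)
  ild <- vapply(bands, function(b) {
    vapply(irs, compute_ild, numeric(1), band = b)
  }, numeric(length(irs)))
  ild <- matrix(ild, nrow = length(irs), ncol = length(bands))
  colnames(ild) <- vapply(bands, function(b) paste0(b[1], "_", b[2]), character(1))
  structure(list(angles = angles, itd_us = itd, ild_db = ild, bands = bands,
                 mic_site = irs[[1]]$mic_site),
            class = "cue_curve")
}

#' @export
as.data.frame.cue_curve <- function(x, ...) {
  df <- data.frame(angle_deg = x$angles, itd_us = x$itd_us)
  ild <- as.data.frame(x$ild_db)
  names(ild) <- paste0("ild_db_", colnames(x$ild_db))
  cbind(df, ild)
}

# Pull the selected cue series out of a curve.
cue_values <- function(curve, quantity = c("itd", "ild"), band = 1) {
  quantity <- match.arg(quantity)
  if (quantity == "itd") curve$itd_us else curve$ild_db[, band]
}

#' Summarize cue half-ranges across recording sessions
#'
#' For each curve the half-range is `(max - min) / 2` of the selected cue over
#' the measured angle grid (the "+/- X" reading of a reported cue range); the
#' summary gives the minimum, median and maximum half-range across curves.
#'
#' @param curves list of [build_cue_curve()] results.
#' @param quantity `"itd"` (microseconds) or `"ild"` (dB).
#' @param band band index for ILD curves (ignored for ITD).
#' @return object of class `range_summary`: `half_ranges`, `min`, `median`,
#'   `max`, `quantity`.
#' @export
summarize_ranges <- function(curves, quantity = c("itd", "ild"), band = 1) {
  quantity <- match.arg(quantity)
  if (length(curves) == 0) stop("no curves supplied")
  hr <- vapply(curves, function(cv) {
    v <- cue_values(cv, quantity, band)
    (max(v) - min(v)) / 2
  }, numeric(1))
  structure(list(half_ranges = hr, min = min(hr),
                 median = stats::median(hr), max = max(hr),
                 quantity = quantity),
            class = "range_summary")
}

#' Align a cue curve on its zero crossing (F0)
#'
#' Finds the lateral angle F0 at which the selected cue crosses zero, by
#' linear interpolation between the bracketing grid angles (crossing nearest
#' 0 degrees if there are several), and relabels every angle as
#' `angle - F0`. Cue values are unchanged; only the angle axis shifts. Used to
#' compare the shapes of repeated recordings independently of their offset.
#'
#' @param curve a [build_cue_curve()] result.
#' @param quantity `"itd"` or `"ild"`.
#' @param band band index for ILD (ignored for ITD).
#' @return the curve with shifted angles and an `f0_deg` attribute.
#' @export
align_zero_crossing <- function(curve, quantity = c("itd", "ild"), band = 1) {
  quantity <- match.arg(quantity)
  v <- cue_values(curve, quantity, band)
  a <- curve$angles
  f0s <- numeric(0)
  for (i in seq_len(length(v) - 1)) {
    if (v[i] == 0) {
      f0s <- c(f0s, a[i])
    } else if (v[i] * v[i + 1] < 0) {
      f0s <- c(f0s, a[i] - v[i] * (a[i + 1] - a[i]) / (v[i + 1] - v[i]))
    }
  }
  if (v[length(v)] == 0) f0s <- c(f0s, a[length(a)])
  if (length(f0s) == 0) stop("cue never crosses zero; no F0 exists")
  f0 <- f0s[which.min(abs(f0s))]
  curve$angles <- curve$angles - f0
  attr(curve, "f0_deg") <- f0
  curve
}
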