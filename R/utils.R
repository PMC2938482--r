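# Internal helpers shared across modules.

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

rms <- function(x) sqrt(mean(x^2))

#' Root-mean-square level in decibels
#'
#' Level of a single-channel signal as `20 * log10(RMS / reference)`.
#' With `reference` set to the calibrated pressure corresponding to 0 dB SPL
#' the result is a sound level in dB SPL.
#'
#' @param x numeric vector of calibrated samples.
#' @param reference positive scalar; the pressure (same units as `x`) mapping
#'   to 0 dB.
#' @return level in dB re `reference`.
#' @export
rms_level_db <- function(x, reference = 1) {
  if (length(x) == 0) stop("empty signal")
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0) {
    stop("reference must be a positive scalar")
  }
  r <- rms(x)
  if (r == 0) stop("all-zero signal has no defined level")
  20 * log10(r / reference)
}

# Cross-correlation of x against a shorter kernel y at non-negative lags:
# cc[k + 1] = sum_n x[n + k] * y[n], k = 0 .. length(x) - length(y).
# FFT-based; used by the Golay deconvolution.
cross_correlate_valid <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < ny) stop("signal shorter than kernel")
  n <- stats::nextn(nx + ny - 1, 2)
  X <- stats::fft(c(x, rep(0, n - nx)))
  Y <- stats::fft(c(y, rep(0, n - ny)))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / n
  cc[seq_len(nx - ny + 1)]
}

# Full convolution via FFT: length(x) + length(h) - 1 samples.
convolve_full <- function(x, h) {
  nx <- length(x)
  nh <- length(h)
  n <- stats::nextn(nx + nh - 1, 2)
  X <- stats::fft(c(x, rep(0, n - nx)))
  H <- stats::fft(c(h, rep(0, n - nh)))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(nx + nh - 1)] / n
}

# Evaluate a function under a fixed RNG seed without disturbing the caller's
# RNG state. Every generator draws from its own stream this way.
with_fixed_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
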