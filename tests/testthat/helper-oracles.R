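# Independent oracles used across the suite. These deliberately avoid the
# package's own signal path: direct O(n^2) convolution, FFT upsampling plus
# brute-force correlation, and Parseval band energies.

# Direct (double-loop) convolution; oracle for the FFT-based paths.
direct_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1
  out <- numeric(n)
  for (i in seq_along(h)) {
    out[(i):(i + length(x) - 1)] <- out[(i):(i + length(x) - 1)] + h[i] * x
  }
  out
}

# FFT zero-padding upsampler (band-limited interpolation by factor f).
upsample_fft <- function(x, f) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * f
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  h <- n %/% 2
  Y[1:h] <- X[1:h]
  Y[(m - h + 1):m] <- X[(n - h + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Integer-lag cross-correlation peak on f-times upsampled channels
# (circular, FFT-accelerated); the reference for sub-sample ITD estimates.
# No parabolic interpolation: resolution is one upsampled sample.
oracle_itd_us <- function(ir, factor = 64, max_lag_us = 1250) {
  L <- upsample_fft(ir$left_ir, factor)
  R <- upsample_fft(ir$right_ir, factor)
  n <- length(L)
  cc <- Re(stats::fft(stats::fft(L) * Conj(stats::fft(R)), inverse = TRUE)) / n
  K <- round(max_lag_us * ir$fs * factor / 1e6)
  lags <- -K:K
  idx <- ifelse(lags >= 0, lags + 1, n + lags + 1)
  lags[which.max(cc[idx])] / (ir$fs * factor) * 1e6
}

# Parseval band-energy ratio in dB between two channels.
oracle_band_ratio_db <- function(left, right, fs, band) {
  n <- length(left)
  f <- (0:(n - 1)) * fs / n
  keep <- f >= band[1] & f <= band[2]
  el <- sum(Mod(stats::fft(left))[keep]^2)
  er <- sum(Mod(stats::fft(right))[keep]^2)
  10 * log10(er / el)
}

# Band-limited fractional-delay pair: windowed-sinc kernels a half-delay
# apart, for delay d in samples (positive = left lags).
sinc_delay_pair <- function(d_samples, n = 256, fs = 80000) {
  k <- 0:(n - 1)
  sincf <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  centre <- n / 2
  impulse_response_pair(sincf(k - centre - d_samples / 2),
                        sincf(k - centre + d_samples / 2),
                        fs, source_angle = NA_real_)
}

# Closed-form Woodworth delay (independent restatement used as the oracle
# for the generator's geometry).
oracle_woodworth_s <- function(angle_deg, radius, c = 343) {
  th <- abs(angle_deg)
  th <- ifelse(th > 90, 180 - th, th)
  sign(angle_deg) * (radius / c) * (sin(th * pi / 180) + th * pi / 180)
}
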