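# Auditory spectrogram front end.
#
# The encoding models take as input a cochlear-style representation: a bank
# of fourth-order gammatone filters on the ERB scale (180-7000 Hz), each
# band's output half-wave rectified, compressed, sharpened across bands and
# smoothed by a leaky integrator, then reduced to 32 bands at 50 Hz.

# Glasberg-Moore ERB-rate scale
erb_number <- function(f_hz) 21.4 * log10(4.37 * f_hz / 1000 + 1)
erb_number_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
erb_bandwidth <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

erb_centers <- function(n_bands, f_lo = 180, f_hi = 7000) {
  erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi),
                     length.out = n_bands))
}

# FIR gammatone impulse response, order 4, peak gain normalized to 1 at fc
gammatone_ir <- function(fc, rate, dur = 0.064) {
  t <- seq(0, dur, by = 1 / rate)
  b <- 1.019 * erb_bandwidth(fc)
  h <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  # normalize the magnitude response at fc to unity
  H <- sum(h * exp(-2i * pi * fc * t))
  h / Mod(H)
}

fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- next_pow2(n)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                       stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_along(x)]
}

# Zero-phase FFT-domain low-pass with a raised-cosine edge (10% of cutoff).
# Used for anti-aliasing slowly varying envelopes, where an IIR design with a
# very small normalized cutoff would be numerically fragile.
fft_lowpass <- function(x, rate, cutoff) {
  n <- length(x)
  f <- fft_freqs(n, rate)
  gain <- lowpass_gain(f, cutoff, 0.1)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Gammatone auditory spectrogram
#'
#' @param wave Mono waveform.
#' @param audio_rate Sample rate in Hz; must be at least twice the top band
#'   (14 kHz).
#' @param n_bands Number of gammatone bands (default 128, ERB-spaced
#'   180-7000 Hz).
#' @param compression Compression exponent applied to the rectified band
#'   output (default 1/3, cube root).
#' @param sharpen Apply first-difference spectral sharpening across bands
#'   (half-wave rectified lateral-inhibition approximation); default `TRUE`.
#' @param integrator_tau Leaky-integrator time constant in seconds
#'   (default 8 ms).
#' @return Object of class `aud_spectrogram`: `values` (time x band,
#'   non-negative), `band_centers` (Hz), `rate` (Hz, native audio rate here).
#' @export
gammatone_spectrogram <- function(wave, audio_rate, n_bands = 128,
                                  compression = 1 / 3, sharpen = TRUE,
                                  integrator_tau = 0.008) {
  check_scalar(audio_rate, "audio_rate", lower = 14000)
  wave <- as.numeric(wave)
  centers <- erb_centers(n_bands)
  n <- length(wave)
  hlen <- length(gammatone_ir(centers[1], audio_rate))
  nfft <- next_pow2(n + hlen - 1)
  X <- stats::fft(c(wave, numeric(nfft - n)))
  # convolve two real impulse responses per complex FFT (x is real, so
  # ifft(X * fft(h1 + i*h2)) carries band 1 in Re and band 2 in Im)
  env <- matrix(0, n, n_bands)
  for (b in seq(1, n_bands, by = 2)) {
    h1 <- gammatone_ir(centers[b], audio_rate)
    hc <- if (b + 1 <= n_bands)
      h1 + 1i * gammatone_ir(centers[b + 1], audio_rate) else h1
    H <- stats::fft(c(hc, numeric(nfft - length(hc))))
    y <- stats::fft(X * H, inverse = TRUE)[1:n] / nfft
    env[, b] <- pmax(Re(y), 0)^compression
    if (b + 1 <= n_bands) env[, b + 1] <- pmax(Im(y), 0)^compression
  }
  if (sharpen) {
    sharp <- env
    sharp[, -1] <- pmax(env[, -1] - env[, -ncol(env)], 0)
    env <- sharp
  }
  a <- exp(-1 / (integrator_tau * audio_rate))
  out <- apply(env, 2, function(x)
    as.numeric(stats::filter(x * (1 - a), a, method = "recursive")))
  structure(list(values = out, band_centers = centers, rate = audio_rate),
            class = "aud_spectrogram")
}

#' Reduce band count and resample an auditory spectrogram
#'
#' Averages adjacent bands in equal blocks (128 -> 32 with the defaults),
#' anti-alias low-pass filters each reduced band at `rate/2` and resamples to
#' `rate`.  Band centres of merged blocks become geometric means.
#'
#' @param spec An `aud_spectrogram`.
#' @param n_out Number of output bands; must divide the input band count.
#' @param rate Output sample rate in Hz (default 50).
#' @return An `aud_spectrogram` at the reduced resolution.
#' @export
reduce_and_resample <- function(spec, n_out = 32, rate = 50) {
  stopifnot(inherits(spec, "aud_spectrogram"))
  n_in <- ncol(spec$values)
  if (n_in %% n_out != 0)
    stop_invalid("band count %d not divisible by n_out = %d", n_in, n_out)
  fac <- n_in / n_out
  grp <- rep(seq_len(n_out), each = fac)
  reduced <- t(rowsum(t(spec$values), grp) / fac)
  centers <- exp(rowsum(log(spec$band_centers), grp) / fac)[, 1]
  n_time_out <- max(1L, floor(nrow(reduced) * rate / spec$rate))
  if (spec$rate > 2 * rate) {
    reduced <- apply(reduced, 2, fft_lowpass, rate = spec$rate,
                     cutoff = rate / 2)
  }
  vals <- apply(reduced, 2, linear_resample, from_rate = spec$rate,
                to_rate = rate, n_out = n_time_out)
  vals <- matrix(pmax(vals, 0), nrow = n_time_out)
  structure(list(values = vals, band_centers = centers, rate = rate),
            class = "aud_spectrogram")
}

#' Full auditory-feature path: waveform to 32-band, 50 Hz spectrogram
#'
#' @inheritParams gammatone_spectrogram
#' @param rate Output rate (Hz).
#' @param n_out Output band count.
#' @param ... Passed to [gammatone_spectrogram()].
#' @return An `aud_spectrogram` at `rate` Hz with `n_out` bands.
#' @export
auditory_spectrogram <- function(wave, audio_rate, rate = 50, n_out = 32,
                                 ...) {
  reduce_and_resample(gammatone_spectrogram(wave, audio_rate, ...),
                      n_out = n_out, rate = rate)
}
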