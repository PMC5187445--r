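# Modulation power spectrum (MPS) analysis and modulation-domain filtering.
#
# Speech carries its intelligibility in a restricted region of the joint
# spectrotemporal modulation space: slow temporal modulations (syllables,
# words) and low spectral modulations (formants), with harmonic pitch
# structure at high spectral modulations.  Degraded speech is produced here by
# low-pass filtering the 2D Fourier transform of a log-amplitude spectrogram
# along one modulation axis, then inverting the filtered spectrogram back to a
# waveform by iterative phase retrieval.

#' Gaussian-window log-amplitude spectrogram
#'
#' Short-time Fourier analysis with a Gaussian window, the standard front end
#' for modulation power spectrum work: the Gaussian's joint time-frequency
#' concentration gives a smooth spectrogram whose 2D transform is easy to
#' interpret.
#'
#' @param wave Mono waveform (numeric vector).
#' @param audio_rate Sample rate in Hz.
#' @param window_sigma Gaussian window standard deviation in seconds.  The
#'   default 7.1 ms trades spectral resolution (about 22 Hz) against temporal
#'   resolution as is standard for speech modulation analysis.
#' @param time_step Hop between analysis frames in seconds (default 2 ms).
#' @param floor_db Dynamic range: values are clipped at `max - floor_db` dB.
#' @return An object of class `mod_spectrogram`: list with `values` (time x
#'   frequency dB matrix, maximum at 0 dB), `freqs` (Hz), `times` (s),
#'   `ref_db` (absolute level of the 0 dB reference), window bookkeeping used
#'   by [invert_spectrogram()], and the originating sample rate.
#' @export
compute_spectrogram <- function(wave, audio_rate, window_sigma = 0.0071,
                                time_step = 0.002, floor_db = 50) {
  check_scalar(audio_rate, "audio_rate", lower = 1)
  check_scalar(window_sigma, "window_sigma", lower = 0, strict_lower = TRUE)
  check_scalar(time_step, "time_step", lower = 0, strict_lower = TRUE)
  check_scalar(floor_db, "floor_db", lower = 0, strict_lower = TRUE)
  wave <- as.numeric(wave)
  if (length(wave) < 6 * window_sigma * audio_rate)
    stop_invalid("waveform too short: need at least %d samples",
                 ceiling(6 * window_sigma * audio_rate))
  hop <- max(1L, as.integer(round(time_step * audio_rate)))
  half <- as.integer(ceiling(3 * window_sigma * audio_rate))
  win <- exp(-0.5 * ((-half:half) / (window_sigma * audio_rate))^2)
  L <- length(win)
  nfft <- next_pow2(L)
  n <- length(wave)
  centers <- seq.int(1L, n, by = hop)
  padded <- c(numeric(half), wave, numeric(half + nfft))
  frames <- vapply(centers, function(c0) {
    seg <- padded[c0:(c0 + L - 1)] * win
    c(seg, numeric(nfft - L))
  }, numeric(nfft))
  S <- stats::mvfft(frames)[1:(nfft / 2 + 1), , drop = FALSE]
  mag <- Mod(S)
  ref <- max(mag)
  vals <- if (ref == 0) matrix(-floor_db, nrow(mag), ncol(mag)) else
    pmax(20 * log10(pmax(mag / ref, .Machine$double.xmin)), -floor_db)
  structure(list(
    values = t(vals),                        # time x frequency
    freqs = (0:(nfft / 2)) * audio_rate / nfft,
    times = (centers - 1) / audio_rate,
    time_step = hop / audio_rate,
    window_sigma = window_sigma,
    floor_db = floor_db,
    ref_db = if (ref == 0) -Inf else 20 * log10(ref),
    rate = audio_rate,
    n_samples = n,
    window = win, hop = hop, nfft = nfft
  ), class = "mod_spectrogram")
}

#' Modulation power spectrum of a spectrogram
#'
#' The 2D Fourier transform of the mean-subtracted log spectrogram.  The
#' temporal modulation axis (`wt`, Hz) is signed; the spectral modulation axis
#' (`wf`, cycles/kHz) is folded to non-negative values using the conjugate
#' symmetry of the real-input transform.  The amplitude part is the MPS.
#'
#' @param spec A `mod_spectrogram`.
#' @return Object of class `mod_spectrum`: `complex_values` (folded wt x wf
#'   matrix, wt ascending), `wt` (Hz), `wf` (cycles/kHz), `amplitude`,
#'   `source_shape`, and the unfolded transform in `complex_full` for exact
#'   power accounting.
#' @export
compute_mps <- function(spec) {
  stopifnot(inherits(spec, "mod_spectrogram"))
  X <- spec$values - mean(spec$values)
  F2 <- stats::fft(X)
  nt <- nrow(X); nf <- ncol(X)
  wt <- fft_freqs(nt, 1 / spec$time_step)
  df <- spec$freqs[2] - spec$freqs[1]
  wf <- fft_freqs(nf, 1 / df) * 1000       # cycles/Hz -> cycles/kHz
  ord_t <- order(wt)
  keep_f <- which(wf >= 0)
  keep_f <- keep_f[order(wf[keep_f])]
  structure(list(
    complex_values = F2[ord_t, keep_f, drop = FALSE],
    amplitude = Mod(F2[ord_t, keep_f, drop = FALSE]),
    wt = wt[ord_t],
    wf = wf[keep_f],
    source_shape = dim(X),
    complex_full = F2,
    source_power = sum(X^2)
  ), class = "mod_spectrum")
}

#' Construct a modulation low-pass filter
#'
#' @param kind `"spectral_lowpass"` or `"temporal_lowpass"`.
#' @param corner Corner of the low-pass: cycles/kHz for the spectral filter
#'   (study value 0.5), Hz for the temporal filter (study value 3).
#' @param transition_width Raised-cosine transition band width as a fraction
#'   of the corner (default 0.2); 0 gives a brick wall.
#' @return Object of class `modulation_filter`.
#' @export
modulation_filter <- function(kind = c("spectral_lowpass", "temporal_lowpass"),
                              corner = NULL, transition_width = 0.2) {
  kind <- match.arg(kind)
  if (is.null(corner))
    corner <- if (kind == "spectral_lowpass") 0.5 else 3
  check_scalar(corner, "corner", lower = 0, strict_lower = TRUE)
  check_scalar(transition_width, "transition_width", lower = 0)
  structure(list(kind = kind, corner = corner,
                 transition_width = transition_width),
            class = "modulation_filter")
}

lowpass_gain <- function(freqs, corner, width) {
  a <- abs(freqs)
  if (width <= 0) return(as.numeric(a <= corner))
  edge <- corner * (1 + width)
  g <- numeric(length(a))
  g[a <= corner] <- 1
  tr <- a > corner & a < edge
  g[tr] <- 0.5 * (1 + cos(pi * (a[tr] - corner) / (corner * width)))
  g
}

#' Low-pass filter a spectrogram in the modulation domain
#'
#' The gain of stop-band modulation components is set to zero (with an
#' optional raised-cosine transition); pass-band modulation phase is
#' untouched.  By default the coarse per-band time-averaged power profile is
#' restored after filtering so that the overall frequency power spectrum of
#' the sound is unchanged; for a spectral filter the restoring profile is
#' itself smoothed below the filter corner, so the fine spectral structure
#' (for example harmonic ripple) that the filter removed is not
#' re-introduced.
#'
#' @param spec A `mod_spectrogram`.
#' @param filt A [modulation_filter()].
#' @param restore_power Restore the per-band time-averaged power profile
#'   (default `TRUE`).
#' @return A filtered `mod_spectrogram` with the same grids.
#' @export
apply_modulation_filter <- function(spec, filt, restore_power = TRUE) {
  stopifnot(inherits(spec, "mod_spectrogram"),
            inherits(filt, "modulation_filter"))
  X <- spec$values
  nt <- nrow(X); nf <- ncol(X)
  F2 <- stats::fft(X)
  if (filt$kind == "temporal_lowpass") {
    wt <- fft_freqs(nt, 1 / spec$time_step)
    gain <- lowpass_gain(wt, filt$corner, filt$transition_width)
    F2 <- F2 * gain
  } else {
    df <- spec$freqs[2] - spec$freqs[1]
    wf <- fft_freqs(nf, 1 / df) * 1000
    gain <- lowpass_gain(wf, filt$corner, filt$transition_width)
    F2 <- sweep(F2, 2, gain, `*`)
  }
  Y <- Re(stats::fft(F2, inverse = TRUE)) / (nt * nf)
  if (restore_power) {
    A0 <- 10^(X / 20)
    A1 <- 10^(Y / 20)
    scale_db <- 10 * log10(colMeans(A0^2) / pmax(colMeans(A1^2),
                                                 .Machine$double.xmin))
    if (filt$kind == "spectral_lowpass") {
      # restore only the coarse spectral profile: fine structure above the
      # corner was deliberately removed
      df_khz <- (spec$freqs[2] - spec$freqs[1]) / 1000
      scale_db <- fft_lowpass(scale_db, rate = 1 / df_khz,
                              cutoff = filt$corner)
    }
    Y <- sweep(Y, 2, scale_db, `+`)
  }
  out <- spec
  out$values <- pmax(Y, max(Y) - spec$floor_db)
  out
}

#' Invert a spectrogram to a waveform by iterative phase retrieval
#'
#' Alternating-projection phase recovery: starting from seeded random phases,
#' repeatedly resynthesize a waveform by overlap-add, reanalyze it, keep the
#' new phases and replace the magnitudes with the target.  This is the
#' classical iterative spectrogram-inversion scheme; the returned waveform's
#' spectrogram magnitude approximates the input.
#'
#' @param spec A `mod_spectrogram`.
#' @param audio_rate Output sample rate; must equal the analysis rate.
#' @param n_iter Number of iterations (>= 1; 30 is a good default).
#' @param seed Seed for the random phase initialization.
#' @return Waveform (numeric vector of the original length) with attribute
#'   `magnitude_error`, the final relative magnitude error
#'   `||abs(STFT(x)) - M|| / ||M||`.  If the error increases on three
#'   consecutive iterations a warning is raised and the best iterate is
#'   returned.
#' @export
invert_spectrogram <- function(spec, audio_rate = spec$rate, n_iter = 30,
                               seed = 1) {
  stopifnot(inherits(spec, "mod_spectrogram"))
  if (!isTRUE(all.equal(audio_rate, spec$rate)))
    stop_invalid("audio_rate must match the analysis rate (%g Hz)", spec$rate)
  if (n_iter < 1) stop_invalid("n_iter must be >= 1")
  M <- t(10^((spec$values + spec$ref_db) / 20))   # frequency x time, linear
  if (!is.finite(spec$ref_db)) M[] <- 0
  nfft <- spec$nfft; hop <- spec$hop; win <- spec$window
  L <- length(win); half <- (L - 1) %/% 2
  nframes <- ncol(M)
  n_pad <- (nframes - 1) * hop + L
  # overlap-add normalization for the synthesis window
  wsum <- numeric(n_pad)
  for (k in seq_len(nframes)) {
    i0 <- (k - 1) * hop
    wsum[(i0 + 1):(i0 + L)] <- wsum[(i0 + 1):(i0 + L)] + win^2
  }
  wsum <- pmax(wsum, 1e-8 * max(wsum))
  stft_mag_phase <- function(x) {
    frames <- vapply(seq_len(nframes), function(k) {
      i0 <- (k - 1) * hop
      c(x[(i0 + 1):(i0 + L)] * win, numeric(nfft - L))
    }, numeric(nfft))
    stats::mvfft(frames)[1:(nfft / 2 + 1), , drop = FALSE]
  }
  istft <- function(S) {
    full <- rbind(S, Conj(S[(nfft / 2):2, , drop = FALSE]))
    frames <- Re(stats::mvfft(full, inverse = TRUE)) / nfft
    x <- numeric(n_pad)
    for (k in seq_len(nframes)) {
      i0 <- (k - 1) * hop
      x[(i0 + 1):(i0 + L)] <- x[(i0 + 1):(i0 + L)] + frames[1:L, k] * win
    }
    x / wsum
  }
  phase <- with_seed(seed,
                     matrix(stats::runif(length(M), 0, 2 * pi), nrow(M)))
  mag_err <- function(S) sqrt(sum((Mod(S) - M)^2)) /
    max(sqrt(sum(M^2)), .Machine$double.xmin)
  best <- NULL; best_err <- Inf; n_up <- 0L; prev_err <- Inf
  x <- istft(M * exp(1i * phase))
  diverged <- FALSE
  for (it in seq_len(n_iter)) {
    S <- stft_mag_phase(x)
    err <- mag_err(S)
    if (err < best_err) { best <- x; best_err <- err }
    n_up <- if (err > prev_err) n_up + 1L else 0L
    if (n_up >= 3L) {
      warning("spectrogram inversion diverging; returning best iterate")
      diverged <- TRUE
      break
    }
    prev_err <- err
    phase <- Arg(S)
    x <- istft(M * exp(1i * phase))
  }
  if (!diverged) {
    err <- mag_err(stft_mag_phase(x))
    if (err < best_err) { best <- x; best_err <- err }
  }
  out <- best[(half + 1):(half + spec$n_samples)]
  attr(out, "magnitude_error") <- best_err
  out
}

#' Create modulation-filtered (degraded) speech
#'
#' Composition of [compute_spectrogram()], [apply_modulation_filter()] and
#' [invert_spectrogram()]; the output RMS is matched to the input RMS.
#'
#' @inheritParams compute_spectrogram
#' @param filt A [modulation_filter()].
#' @param n_iter Phase-retrieval iterations.
#' @param seed Seed for the phase initialization.
#' @param ... Passed to [compute_spectrogram()].
#' @return Filtered waveform, same length and RMS as the input.
#' @export
synthesize_filtered_speech <- function(wave, audio_rate, filt, n_iter = 30,
                                       seed = 1, ...) {
  spec <- compute_spectrogram(wave, audio_rate, ...)
  spec_f <- apply_modulation_filter(spec, filt)
  y <- invert_spectrogram(spec_f, audio_rate, n_iter = n_iter, seed = seed)
  err <- attr(y, "magnitude_error")
  y <- y * (rms(wave) / max(rms(y), .Machine$double.xmin))
  attr(y, "magnitude_error") <- err
  y
}
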