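# Synthetic experiment generator.
#
# Emulates the three-condition filtered-speech listening task with known
# ground truth: speech-like stimuli (harmonic stacks with drifting pitch,
# slowly moving formant peaks, a syllabic envelope and brief plosive-like
# bursts), modulation-filtered BEFORE/AFTER versions that are bit-identical
# within a trial, and electrode HFB responses generated as the causal linear
# convolution of a ground-truth STRF with the auditory spectrogram plus
# additive noise.  The AFTER-condition truth is shifted partway toward the
# MIDDLE-condition truth by the coefficient lambda, which is the plasticity
# the downstream pipeline must detect.

#' Configuration of a synthetic experiment
#'
#' @param n_trials Number of trials (>= 2; each trial is a unique sentence).
#' @param n_electrodes Number of simulated electrodes.
#' @param audio_rate Audio sample rate in Hz (>= 14 kHz).
#' @param trial_duration Stimulus duration in seconds (2-5 s).
#' @param snr Linear signal-to-noise ratio of the simulated HFB (> 0; may be
#'   `Inf` for noiseless simulations).
#' @param shift_lambda Plasticity shift in `[0, 1]`: 0 means the AFTER truth
#'   equals the BEFORE truth, 1 means it equals the MIDDLE truth.
#' @param seed Master seed; all per-trial and per-electrode randomness is
#'   derived from it with [derive_seed()].
#' @param filter_type `"temporal_lowpass"` (corner 3 Hz) or
#'   `"spectral_lowpass"` (corner 0.5 cycles/kHz).
#' @param noise_model `"white"` (default) or `"ar1"` (coefficient 0.7;
#'   temporally correlated, closer to real HFB noise).
#' @param n_gabors Number of Gabor components per ground-truth STRF
#'   (default 1; more gives less stereotyped truths).
#' @param hfb_rate Simulation/analysis rate in Hz (default 50).
#' @param pad_pre,pad_post Silence padding around each stimulus in seconds
#'   (gives every epoch a pre-stimulus baseline).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_trials = 10, n_electrodes = 30,
                             audio_rate = 16000, trial_duration = 3,
                             snr = 4, shift_lambda = 0.8, seed = 1,
                             filter_type = c("temporal_lowpass",
                                             "spectral_lowpass"),
                             noise_model = c("white", "ar1"),
                             n_gabors = 1, hfb_rate = 50,
                             pad_pre = 1.0, pad_post = 0.6) {
  filter_type <- match.arg(filter_type)
  noise_model <- match.arg(noise_model)
  if (n_trials < 2) stop_invalid("n_trials must be >= 2 (jackknife folds)")
  check_scalar(trial_duration, "trial_duration", lower = 2, upper = 5)
  if (!(is.numeric(snr) && length(snr) == 1 && snr > 0))
    stop_invalid("snr must be a positive number (possibly Inf)")
  check_scalar(shift_lambda, "shift_lambda", lower = 0, upper = 1)
  check_scalar(audio_rate, "audio_rate", lower = 14000)
  structure(list(n_trials = as.integer(n_trials),
                 n_electrodes = as.integer(n_electrodes),
                 audio_rate = audio_rate, trial_duration = trial_duration,
                 snr = snr, shift_lambda = shift_lambda,
                 seed = as.integer(seed), filter_type = filter_type,
                 noise_model = noise_model, n_gabors = n_gabors,
                 hfb_rate = hfb_rate, pad_pre = pad_pre,
                 pad_post = pad_post), class = "synthetic_config")
}

# smooth random trajectory through `k` control points, length n
smooth_trajectory <- function(n, k = 4, lo = 0, hi = 1) {
  pts <- stats::runif(k, lo, hi)
  stats::spline(seq(0, 1, length.out = k), pts, xout = seq(0, 1,
                                                           length.out = n),
                method = "natural")$y
}

#' Generate a speech-like synthetic sound
#'
#' A harmonic stack whose fundamental drifts between 90 and 250 Hz, shaped
#' by 2-4 slowly moving formant-like spectral peaks, gated by a syllabic
#' amplitude envelope (3-8 Hz), with brief broadband bursts standing in for
#' plosives.  Peak amplitude is normalized to 0.9 full scale.  Not
#' intelligible speech: a stimulus whose modulation power spectrum is
#' concentrated where speech concentrates it.
#'
#' @param duration Duration in seconds (> 0.5).
#' @param audio_rate Sample rate in Hz.
#' @param seed RNG seed; identical seeds give bit-identical waveforms.
#' @return Mono waveform of exactly `duration * audio_rate` samples.
#' @export
generate_speech_like_sound <- function(duration, audio_rate, seed = 1) {
  if (!is.numeric(duration) || duration <= 0)
    stop_invalid("duration must be positive")
  if (duration <= 0.5) stop_invalid("duration must exceed 0.5 s")
  n <- round(duration * audio_rate)
  with_seed(seed, {
    t <- (seq_len(n) - 1) / audio_rate
    f0_base <- stats::runif(1, 105, 215)   # speaker pitch; contour drifts
    f0 <- f0_base * (1 + 0.09 * (smooth_trajectory(n, k = 4) - 0.5))
    # glottal jitter (~1%): blurs high harmonics as in natural voices
    jit <- fft_lowpass(stats::rnorm(n), audio_rate, 60)
    f0 <- f0 * (1 + 0.015 * jit / stats::sd(jit))
    phase <- 2 * pi * cumsum(f0) / audio_rate
    # syllable segmentation (3-8 Hz): every syllable gets its own random
    # formant targets and gain, mimicking phoneme-to-phoneme spectral change
    syl_rate <- stats::runif(1, 3, 8)
    n_syl <- max(2L, round(duration * syl_rate))
    bounds <- round(seq(1, n + 1, length.out = n_syl + 1))
    syl_center_t <- (bounds[-1] + bounds[-(n_syl + 1)]) / 2 / audio_rate
    n_formants <- sample(2:4, 1)
    fmt_lo <- log(300); fmt_hi <- log(3400)
    interp_targets <- function(targets) {
      stats::spline(syl_center_t, targets, xout = t, method = "natural")$y
    }
    formants <- lapply(seq_len(n_formants), function(j) {
      base <- fmt_lo + (fmt_hi - fmt_lo) * (j - 0.5 +
                                              stats::runif(n_syl, -0.45,
                                                           0.45)) /
        n_formants
      list(freq = exp(interp_targets(base)),
           amp = pmax(interp_targets(stats::runif(n_syl, 0.1, 1)), 0),
           bw = stats::runif(1, 150, 350))
    })
    n_harm <- max(3L, floor(6200 / max(f0)))
    # spectral tilt varies by syllable (vocal effort / voice quality)
    tilt <- exp(interp_targets(stats::runif(n_syl, log(1600), log(3200))))
    x <- numeric(n)
    for (k in seq_len(n_harm)) {
      fk <- k * f0
      amp <- 0.02 / k
      for (fm in formants)
        amp <- amp + fm$amp * exp(-0.5 * ((fk - fm$freq) / fm$bw)^2)
      amp <- amp / (1 + (fk / tilt)^2)
      x <- x + amp * sin(k * phase)
    }
    # syllabic gating with per-syllable gain
    gains <- stats::runif(n_syl, 0.35, 1)
    env <- numeric(n)
    for (s in seq_len(n_syl)) {
      idx <- bounds[s]:(bounds[s + 1] - 1)
      gate <- pmax(sin(pi * seq_along(idx) / length(idx)), 0)^0.8
      env[idx] <- gains[s] * gate
    }
    # speech envelopes are smooth and rarely fully silent: low-pass the
    # syllabic gate and keep a voicing floor
    env <- pmax(fft_lowpass(env, audio_rate, 10), 0) + 0.08
    # aspiration noise sharing the envelope: fills the dB valleys between
    # harmonics, as breathy voicing does
    asp <- fft_lowpass(stats::rnorm(n), audio_rate, 2500)
    asp_mix <- pmax(interp_targets(stats::runif(n_syl, 0.02, 0.18)), 0)
    x <- (x + asp_mix * max(abs(x)) * asp / max(abs(asp))) * env
    # fricative-like high-frequency noise in a random subset of syllables
    hf_noise <- fft_lowpass(stats::rnorm(n), audio_rate, 6500) -
      fft_lowpass(stats::rnorm(n), audio_rate, 2000)
    for (s in which(stats::runif(n_syl) < 0.35)) {
      idx <- bounds[s]:(bounds[s + 1] - 1)
      gate <- sin(pi * seq_along(idx) / length(idx))^2
      x[idx] <- x[idx] + 0.18 * max(abs(x)) * hf_noise[idx] * gate /
        max(abs(hf_noise))
    }
    # plosive-like band-limited bursts at syllable onsets
    burst_len <- round(0.02 * audio_rate)
    burst_src <- fft_lowpass(stats::rnorm(n), audio_rate, 6000) -
      fft_lowpass(stats::rnorm(n), audio_rate, 1500)
    burst_src <- burst_src / max(abs(burst_src))
    for (s in which(stats::runif(n_syl) < 0.35)) {
      i0 <- bounds[s]
      if (i0 + burst_len - 1 > n) next
      win <- sin(pi * seq_len(burst_len) / burst_len)^2
      x[i0:(i0 + burst_len - 1)] <- x[i0:(i0 + burst_len - 1)] +
        0.15 * max(abs(x)) * burst_src[i0:(i0 + burst_len - 1)] * win
    }
    x * (0.9 / max(abs(x)))
  })
}

# single random 2D Gabor on the (lag, band) grid, in standardized units
random_gabor_strf <- function(n_lag = 21, n_band = 32, lags_s = strf_lags(),
                              n_gabors = 1) {
  g <- matrix(0, n_lag, n_band)
  lag_ms <- lags_s * 1000
  for (i in seq_len(n_gabors)) {
    tau0 <- stats::runif(1, 50, 250)
    p0 <- stats::runif(1, 4, n_band - 3)
    sig_t <- stats::runif(1, 80, 150)
    sig_p <- stats::runif(1, 4, 8)
    w_t <- stats::runif(1, 1, 3.5) / 1000        # cycles per ms
    w_p <- stats::runif(1, 0.02, 0.12)           # cycles per band
    theta <- stats::runif(1, 0, pi)
    phi <- stats::runif(1, 0, 2 * pi)
    dT <- outer(lag_ms - tau0, rep(1, n_band))
    dP <- outer(rep(1, n_lag), seq_len(n_band) - p0)
    carrier <- cos(2 * pi * (w_t * cos(theta) * dT +
                               w_p * sin(theta) * dP) + phi)
    g <- g + exp(-dT^2 / (2 * sig_t^2) - dP^2 / (2 * sig_p^2)) * carrier
  }
  (g - mean(g)) / stats::sd(g)
}

# Reference unfiltered-speech spectrogram (fixed internal seed), used to
# derive the speech-matched tuning component.
speech_reference_spectrogram <- function() {
  cache <- getOption("strfshift.ref_spec")
  if (!is.null(cache)) return(cache)
  snd <- generate_speech_like_sound(2, 16000, seed = 930001L)
  S <- auditory_spectrogram(snd, 16000)$values
  options(strfshift.ref_spec = S)
  S
}

# Speech-matched STRF component: dominant eigenvector of the lag-expanded
# covariance of (standardized) speech-like stimuli -- the filter shape with
# maximal output power to speech.  Standardized and sign-fixed; cached.
speech_matched_component <- function(n_lags = 21) {
  cache <- getOption("strfshift.matched_strf")
  if (!is.null(cache)) return(cache)
  S <- scale(speech_reference_spectrogram())
  X <- build_lagged_design(S, n_lags)
  v1 <- eigen(crossprod(X), symmetric = TRUE)$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  g <- strf_unvec(v1, n_lags, ncol(S))
  g <- (g - mean(g)) / stats::sd(g)
  options(strfshift.matched_strf = g)
  g
}

#' Generate ground-truth STRFs for all electrodes and conditions
#'
#' BEFORE truths are independent random 2D Gabors (standardized to zero
#' mean, unit s.d.).  MIDDLE truths combine an electrode-specific random
#' Gabor with a shared speech-matched component (the dominant eigenvector of
#' the lag-expanded speech-stimulus covariance, an envelope-following filter
#' shape): the unfiltered-speech condition is the one in which cortical
#' tuning matches speech features, and the plasticity hypothesis is a shift
#' toward that tuning.  The AFTER truth is the elementwise interpolation
#' `(1 - lambda) * before + lambda * middle`, so `lambda` is a scale-free
#' shift coefficient in standardized coefficient space.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_truth`: arrays `strf_before`,
#'   `strf_middle`, `strf_after` (lag x band x electrode), plus
#'   `shift_lambda`, `snr`, `seed`, `lags_s`.
#' @export
generate_ground_truth_strfs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lags_s <- strf_lags(config$hfb_rate)
  n_lag <- length(lags_s); n_band <- 32
  mk <- function(cond, matched = NULL) {
    arr <- array(NA_real_, c(n_lag, n_band, config$n_electrodes))
    for (e in seq_len(config$n_electrodes)) {
      g <- with_seed(
        derive_seed(config$seed, "truth", cond, e),
        {
          gab <- random_gabor_strf(n_lag, n_band, lags_s, config$n_gabors)
          if (!is.null(matched)) {
            w <- stats::runif(1, 1.0, 1.8)
            gab <- gab + w * matched
          }
          gab
        })
      arr[, , e] <- (g - mean(g)) / stats::sd(g)
    }
    arr
  }
  before <- mk("before")
  middle <- mk("middle", matched = speech_matched_component(n_lag))
  after <- (1 - config$shift_lambda) * before + config$shift_lambda * middle
  structure(list(strf_before = before, strf_middle = middle,
                 strf_after = after, shift_lambda = config$shift_lambda,
                 snr = config$snr, seed = config$seed, lags_s = lags_s),
            class = "synthetic_truth")
}

#' Simulate an HFB trace as STRF-filtered stimulus plus noise
#'
#' `r(t) = sum_tau sum_p g(tau, p) S(t - tau, p) + eps(t)` with causal lags
#' and `eps` scaled so that `var(signal) / var(eps) = snr`.
#'
#' @param strf_true Lag x band gain matrix.
#' @param spectrogram Time x band stimulus matrix (or `aud_spectrogram`);
#'   band count must match the STRF.
#' @param snr Linear signal-to-noise ratio (`Inf` for no noise).
#' @param seed RNG seed for the noise.
#' @param noise_model `"white"` or `"ar1"` (coefficient 0.7).
#' @return Numeric response trace of length `nrow(spectrogram)`.
#' @export
simulate_hfb <- function(strf_true, spectrogram, snr = Inf, seed = 1,
                         noise_model = c("white", "ar1")) {
  noise_model <- match.arg(noise_model)
  if (inherits(spectrogram, "aud_spectrogram"))
    spectrogram <- spectrogram$values
  strf_true <- as.matrix(strf_true)
  spectrogram <- as.matrix(spectrogram)
  if (ncol(spectrogram) != ncol(strf_true))
    stop_invalid("band axis mismatch: stimulus has %d bands, STRF has %d",
                 ncol(spectrogram), ncol(strf_true))
  sig <- as.numeric(build_lagged_design(spectrogram, nrow(strf_true)) %*%
                      strf_vec(strf_true))
  if (!is.finite(snr)) return(sig)
  target_var <- stats::var(sig) / snr
  eps <- with_seed(seed, {
    if (noise_model == "white") {
      stats::rnorm(length(sig), sd = sqrt(target_var))
    } else {
      a <- 0.7
      innov <- stats::rnorm(length(sig),
                            sd = sqrt(target_var * (1 - a^2)))
      as.numeric(stats::filter(innov, a, method = "recursive"))
    }
  })
  sig + eps
}

#' Generate the stimulus arm of a synthetic experiment
#'
#' One unique speech-like sound per trial; its modulation-filtered version
#' (used identically for BEFORE and AFTER) and the unfiltered version (used
#' for MIDDLE), padded with silence, plus their reduced auditory
#' spectrograms.  Separated from the response simulation so expensive audio
#' synthesis can be shared across simulations with different truths or noise.
#'
#' @param config A [synthetic_config()].
#' @return List with `audio` (per trial: `filtered`, `unfiltered`, unpadded),
#'   `spec` (per condition name: time x band x trial array at `hfb_rate`),
#'   `times` (epoch axis, s relative to stimulus onset), and grid metadata.
#' @export
generate_stimulus_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  filt <- modulation_filter(config$filter_type)
  n_pre <- round(config$pad_pre * config$audio_rate)
  n_post <- round(config$pad_post * config$audio_rate)
  audio <- vector("list", config$n_trials)
  spec_f <- NULL; spec_u <- NULL
  for (k in seq_len(config$n_trials)) {
    snd <- generate_speech_like_sound(config$trial_duration,
                                      config$audio_rate,
                                      derive_seed(config$seed, "audio", k))
    fsnd <- synthesize_filtered_speech(snd, config$audio_rate, filt,
                                       seed = derive_seed(config$seed,
                                                          "phase", k))
    audio[[k]] <- list(filtered = as.numeric(fsnd), unfiltered = snd)
    pad <- function(x) c(numeric(n_pre), x, numeric(n_post))
    Sf <- auditory_spectrogram(pad(fsnd), config$audio_rate,
                               rate = config$hfb_rate)
    Su <- auditory_spectrogram(pad(snd), config$audio_rate,
                               rate = config$hfb_rate)
    if (is.null(spec_f)) {
      spec_f <- array(NA_real_, c(dim(Sf$values), config$n_trials))
      spec_u <- array(NA_real_, c(dim(Su$values), config$n_trials))
      band_centers <- Sf$band_centers
    }
    spec_f[, , k] <- Sf$values
    spec_u[, , k] <- Su$values
  }
  times <- (seq_len(dim(spec_f)[1]) - 1) / config$hfb_rate - config$pad_pre
  list(audio = audio,
       spec = list(before = spec_f, middle = spec_u, after = spec_f),
       times = times, band_centers = band_centers,
       hfb_rate = config$hfb_rate, audio_rate = config$audio_rate)
}

#' Simulate condition HFB responses from a stimulus set and truths
#'
#' @param stimuli Output of [generate_stimulus_set()].
#' @param truth A `synthetic_truth`.
#' @param config The matching [synthetic_config()] (noise level and seeds).
#' @return Named list (`before`, `middle`, `after`) of electrode x time x
#'   trial arrays.
#' @export
simulate_trial_responses <- function(stimuli, truth, config) {
  conds <- c("before", "middle", "after")
  n_time <- dim(stimuli$spec$before)[1]
  out <- lapply(conds, function(cond) {
    arr <- array(NA_real_, c(config$n_electrodes, n_time, config$n_trials))
    G <- truth[[paste0("strf_", cond)]]
    for (k in seq_len(config$n_trials)) {
      X <- build_lagged_design(stimuli$spec[[cond]][, , k], dim(G)[1])
      sig_all <- X %*% vapply(seq_len(config$n_electrodes),
                              function(e) strf_vec(G[, , e]),
                              numeric(dim(G)[1] * dim(G)[2]))
      for (e in seq_len(config$n_electrodes)) {
        sig <- sig_all[, e]
        if (is.finite(config$snr)) {
          target_var <- stats::var(sig) / config$snr
          eps <- with_seed(derive_seed(config$seed, "noise", cond, k, e), {
            if (config$noise_model == "white") {
              stats::rnorm(n_time, sd = sqrt(target_var))
            } else {
              a <- 0.7
              innov <- stats::rnorm(n_time,
                                    sd = sqrt(target_var * (1 - a^2)))
              as.numeric(stats::filter(innov, a, method = "recursive"))
            }
          })
          sig <- sig + eps
        }
        arr[e, , k] <- sig
      }
    }
    arr
  })
  names(out) <- conds
  out
}

#' Generate a complete synthetic experiment
#'
#' Composes [generate_stimulus_set()], [generate_ground_truth_strfs()] and
#' [simulate_trial_responses()].  Identical configurations give bit-identical
#' results.
#'
#' @param config A [synthetic_config()].
#' @param stimuli Optional precomputed [generate_stimulus_set()] output for
#'   the same audio settings (reused as-is when supplied).
#' @return Object of class `trialset`: `audio`, `spec`, `hfb` (per-condition
#'   electrode x time x trial arrays), `truth`, `times`, grid metadata and
#'   the `config`.
#' @export
generate_experiment <- function(config, stimuli = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(stimuli)) stimuli <- generate_stimulus_set(config)
  truth <- generate_ground_truth_strfs(config)
  hfb <- simulate_trial_responses(stimuli, truth, config)
  structure(list(audio = stimuli$audio, spec = stimuli$spec, hfb = hfb,
                 truth = truth, times = stimuli$times,
                 band_centers = stimuli$band_centers,
                 lags_s = truth$lags_s,
                 n_trials = config$n_trials,
                 n_electrodes = config$n_electrodes,
                 audio_rate = config$audio_rate,
                 hfb_rate = config$hfb_rate,
                 config = config), class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  cat(sprintf(
    "synthetic trial set: %d trials x 3 conditions, %d electrodes\n  %g s stimuli at %g Hz audio; HFB at %g Hz; lambda = %g, snr = %g\n",
    x$n_trials, x$n_electrodes, x$config$trial_duration, x$audio_rate,
    x$hfb_rate, x$truth$shift_lambda, x$truth$snr))
  invisible(x)
}
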