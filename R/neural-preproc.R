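# Raw intracranial signal conditioning and HFB amplitude extraction.
#
# The analysis target is the high-frequency broadband (HFB, ~70-150 Hz)
# amplitude, a proxy for local population firing.  Raw multi-electrode
# recordings are band-passed 0.5-200 Hz, notch-filtered at the line frequency
# and two harmonics, common-average re-referenced (excluding high-variance
# channels), decomposed into 21 narrow bands between 70 and 140 Hz whose
# Hilbert amplitudes are z-scored and averaged, and finally resampled to the
# analysis rates.  All filtering is zero-phase.

#' Condition raw multi-electrode recordings
#'
#' Zero-phase band-pass (0.5-200 Hz), zero-phase notches at the line
#' frequency and its first two harmonics, then common-average re-referencing
#' across retained channels.  Channels whose variance exceeds
#' `bad_channel_factor` times the median channel variance are flagged and
#' excluded from the average (a simple stand-in for visual artifact review).
#'
#' @param raw Electrode x time matrix.
#' @param rate Sample rate in Hz (>= 500).
#' @param line_freq Line frequency in Hz (default 60).
#' @param band Pass band in Hz (default `c(0.5, 200)`).
#' @param bad_channel_factor Variance threshold multiplier (default 5).
#' @return List with `values` (electrode x time, cleaned), `bad_channels`
#'   (integer indices) and `rate`.
#' @export
preprocess_raw <- function(raw, rate, line_freq = 60, band = c(0.5, 200),
                           bad_channel_factor = 5) {
  raw <- as.matrix(raw)
  check_scalar(rate, "rate", lower = 500)
  filt_one <- function(x) {
    hp <- signal::butter(2, band[1] / (rate / 2), type = "high")
    lp <- signal::butter(4, band[2] / (rate / 2), type = "low")
    x <- as.numeric(signal::filtfilt(hp, x))
    x <- as.numeric(signal::filtfilt(lp, x))
    for (h in 1:3) {
      f0 <- line_freq * h
      if (f0 < rate / 2 - 2) {
        bs <- signal::butter(2, c(f0 - 2, f0 + 2) / (rate / 2),
                             type = "stop")
        x <- as.numeric(signal::filtfilt(bs, x))
      }
    }
    x
  }
  cleaned <- t(apply(raw, 1, filt_one))
  v <- apply(cleaned, 1, stats::var)
  bad <- which(v > bad_channel_factor * stats::median(v))
  good <- setdiff(seq_len(nrow(cleaned)), bad)
  car <- if (length(good)) colMeans(cleaned[good, , drop = FALSE]) else
    colMeans(cleaned)
  cleaned <- sweep(cleaned, 2, car)
  list(values = cleaned, bad_channels = bad, rate = rate)
}

hfb_band_centers <- function(n = 21, lo = 70, hi = 140) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Extract high-frequency broadband amplitude
#'
#' 21 log-spaced centre frequencies between 70 and 140 Hz, bandwidth
#' proportional to the centre (default 0.25 x centre).  Per band: zero-phase
#' band-pass, analytic-signal modulus, z-normalization; the normalized band
#' amplitudes are averaged and resampled to 50 Hz (STRF path) with a 100 Hz
#' variant retained (coherence path).
#'
#' @param cleaned Electrode x time matrix (output of [preprocess_raw()]) or
#'   such a list.
#' @param rate Sample rate in Hz (>= 400).
#' @param bw_factor Bandwidth as a fraction of the centre frequency.
#' @return Object of class `hfb_series`: `values` (electrode x time, 50 Hz),
#'   `values100` (electrode x time, 100 Hz), `rate = 50`, `rate100 = 100`.
#' @export
extract_hfb <- function(cleaned, rate, bw_factor = 0.25) {
  if (is.list(cleaned) && !is.null(cleaned$values)) {
    if (missing(rate)) rate <- cleaned$rate
    cleaned <- cleaned$values
  }
  cleaned <- as.matrix(cleaned)
  check_scalar(rate, "rate", lower = 400)
  centers <- hfb_band_centers()
  amp_one <- function(x) {
    acc <- numeric(length(x))
    for (fc in centers) {
      half_bw <- fc * bw_factor / 2
      bp <- signal::butter(2, c(fc - half_bw, fc + half_bw) / (rate / 2),
                           type = "pass")
      xb <- as.numeric(signal::filtfilt(bp, x))
      env <- Mod(analytic_signal(xb))
      acc <- acc + (env - mean(env)) / max(stats::sd(env),
                                           .Machine$double.eps)
    }
    acc / length(centers)
  }
  hfb_native <- t(apply(cleaned, 1, amp_one))
  resample_rows <- function(M, to_rate) {
    sm <- t(apply(M, 1, fft_lowpass, rate = rate, cutoff = to_rate / 2))
    t(apply(sm, 1, linear_resample, from_rate = rate, to_rate = to_rate))
  }
  structure(list(values = resample_rows(hfb_native, 50),
                 values100 = resample_rows(hfb_native, 100),
                 rate = 50, rate100 = 100, band_centers = centers),
            class = "hfb_series")
}

#' Epoch an HFB series and z-score each trial against its baseline
#'
#' @param hfb Electrode x time matrix (or `hfb_series`, using the 50 Hz
#'   values).
#' @param rate Sample rate of `hfb` in Hz.
#' @param onsets Stimulus onset times in samples (1-based column indices).
#' @param window Epoch extent around onset in seconds, `c(start, end)`.
#' @param baseline Baseline window in seconds relative to onset (default
#'   `c(-0.8, -0.1)`).
#' @return List with `epochs` (trial x time x electrode array of z-scored
#'   amplitudes), `times` (s relative to onset), `rate`.
#' @export
epoch_and_baseline <- function(hfb, rate, onsets, window = c(-1, 2.5),
                               baseline = c(-0.8, -0.1)) {
  if (inherits(hfb, "hfb_series")) { rate <- hfb$rate; hfb <- hfb$values }
  hfb <- as.matrix(hfb)
  rel <- seq(round(window[1] * rate), round(window[2] * rate))
  times <- rel / rate
  base_idx <- which(times >= baseline[1] & times <= baseline[2])
  if (length(base_idx) < 2) stop_invalid("baseline window too short")
  n_el <- nrow(hfb)
  epochs <- array(NA_real_, c(length(onsets), length(rel), n_el))
  for (k in seq_along(onsets)) {
    idx <- onsets[k] + rel
    if (min(idx) < 1 || max(idx) > ncol(hfb))
      stop_invalid("epoch %d extends beyond the recording", k)
    seg <- t(hfb[, idx, drop = FALSE])           # time x electrode
    bmean <- colMeans(seg[base_idx, , drop = FALSE])
    bsd <- apply(seg[base_idx, , drop = FALSE], 2, stats::sd)
    epochs[k, , ] <- sweep(sweep(seg, 2, bmean), 2,
                           pmax(bsd, .Machine$double.eps), `/`)
  }
  list(epochs = epochs, times = times, rate = rate)
}

#' Select speech-responsive (Speech-R) electrodes
#'
#' Per electrode, the mean post-stimulus z-scored amplitude of each trial is
#' bootstrapped (resampling trials) to a 99% confidence interval on the
#' across-trial mean; the electrode is Speech-R when the 0.5th percentile of
#' that bootstrap distribution is strictly greater than 0.
#'
#' @param epochs Trial x time x electrode array of baselined z-scores (or the
#'   list from [epoch_and_baseline()]).
#' @param times Time axis (s relative to onset); post-stimulus means are
#'   taken over `times > 0`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return List with `selected` (logical per electrode), `ci_lower`,
#'   `ci_upper`, and `trial_means` (trial x electrode).
#' @export
select_speech_responsive <- function(epochs, times = NULL, n_boot = 10000,
                                     seed = 1) {
  if (is.list(epochs) && !is.null(epochs$epochs)) {
    times <- epochs$times
    epochs <- epochs$epochs
  }
  n_trials <- dim(epochs)[1]
  if (n_trials < 10)
    warning("fewer than 10 trials; bootstrap intervals will be wide")
  post <- if (is.null(times)) seq_len(dim(epochs)[2]) else which(times > 0)
  trial_means <- apply(epochs[, post, , drop = FALSE], c(1, 3), mean)
  n_el <- ncol(trial_means)
  ci <- vapply(seq_len(n_el), function(e)
    bootstrap_ci(trial_means[, e], n_boot = n_boot, level = 0.99,
                 seed = derive_seed(seed, "speechr", e)),
    numeric(2))
  list(selected = ci[1, ] > 0, ci_lower = ci[1, ], ci_upper = ci[2, ],
       trial_means = trial_means)
}
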