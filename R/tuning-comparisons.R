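# Quantifying eSTRF tuning shifts between conditions.
#
# Four complementary views of the same question -- did tuning in the AFTER
# condition move toward the tuning measured on unfiltered speech? --
# 1. the modulation transfer function (MTF) of the fitted eSTRFs,
# 2. the output power of each condition's eSTRF driven by unfiltered speech,
# 3. how well MIDDLE-condition coefficients generalize to filtered trials,
# 4. partial correlations between condition eSTRFs.

#' Modulation transfer function of a STRF
#'
#' Amplitude of the 2D Fourier transform of the (zero-padded) gain tensor.
#' The band axis is first interpolated onto a uniform log-frequency grid so
#' the spectral modulation axis is in cycles per octave, comparable across
#' stimuli and filters; the temporal axis is in Hz.
#'
#' @param gain Lag x band gain matrix (or an `strf_fit`, using its `gain`).
#' @param lags_s Lag grid in seconds (default 0-400 ms at 50 Hz).
#' @param band_centers Band centre frequencies in Hz (default the 32 reduced
#'   ERB centres).
#' @param pad Zero-padding factor for the transform (default 4).
#' @return Object of class `strf_mtf`: `amplitude` (wt x wf), `wt` (Hz,
#'   signed), `wf` (cycles/octave, >= 0).
#' @export
strf_mtf <- function(gain, lags_s = strf_lags(),
                     band_centers = erb_centers(32), pad = 4) {
  if (inherits(gain, "strf_fit")) gain <- gain$gain
  gain <- as.matrix(gain)
  n_lag <- nrow(gain); n_band <- ncol(gain)
  stopifnot(length(lags_s) == n_lag, length(band_centers) == n_band)
  # uniform log2-frequency grid
  lf <- log2(band_centers)
  lf_grid <- seq(min(lf), max(lf), length.out = n_band)
  g_log <- t(apply(gain, 1, function(row)
    stats::approx(lf, row, xout = lf_grid)$y))
  nt <- next_pow2(pad * n_lag); nf <- next_pow2(pad * n_band)
  padded <- matrix(0, nt, nf)
  padded[seq_len(n_lag), seq_len(n_band)] <- g_log
  F2 <- stats::fft(padded)
  dt <- lags_s[2] - lags_s[1]
  dlf <- lf_grid[2] - lf_grid[1]
  wt <- fft_freqs(nt, 1 / dt)
  wf <- fft_freqs(nf, 1 / dlf)
  ord_t <- order(wt)
  keep_f <- which(wf >= 0); keep_f <- keep_f[order(wf[keep_f])]
  structure(list(amplitude = Mod(F2)[ord_t, keep_f, drop = FALSE],
                 wt = wt[ord_t], wf = wf[keep_f]),
            class = "strf_mtf")
}

#' Per-electrode MTF condition contrast (AFTER - BEFORE)
#'
#' Each electrode's MTF difference map is z-scored (zero mean, unit s.d.
#' within the map) so electrodes contribute comparably to group statistics.
#'
#' @param fits_by_condition Named list with `before` and `after` elements,
#'   each a list of `strf_fit` (one per electrode).
#' @param lags_s,band_centers Grids passed to [strf_mtf()].
#' @return List: `maps` (electrode x wt x wf array of z-scored difference
#'   maps), `wt`, `wf`.
#' @export
mtf_condition_contrast <- function(fits_by_condition,
                                   lags_s = strf_lags(),
                                   band_centers = erb_centers(32)) {
  stopifnot(all(c("before", "after") %in% names(fits_by_condition)))
  n_el <- length(fits_by_condition$before)
  first <- strf_mtf(fits_by_condition$before[[1]], lags_s, band_centers)
  maps <- array(NA_real_, c(n_el, length(first$wt), length(first$wf)))
  for (e in seq_len(n_el)) {
    ma <- strf_mtf(fits_by_condition$after[[e]], lags_s, band_centers)
    mb <- strf_mtf(fits_by_condition$before[[e]], lags_s, band_centers)
    d <- ma$amplitude - mb$amplitude
    s <- stats::sd(d)
    maps[e, , ] <- if (s > 0) (d - mean(d)) / s else d
  }
  list(maps = maps, wt = first$wt, wf = first$wf)
}

#' Output power of a STRF driven by unfiltered speech
#'
#' The STRF is z-scored (so only its shape matters), convolved with each
#' stimulus spectrogram (spectrograms standardized as in fitting), and the
#' RMS amplitude of the concatenated predicted traces is returned.  A large
#' value means the filter overlaps strongly with the spectrotemporal
#' structure of the stimuli.
#'
#' @param gain Lag x band gain matrix or `strf_fit`.
#' @param spectrograms List of time x band stimulus matrices (or a single
#'   matrix / `aud_spectrogram`), standardized as in fitting when
#'   `standardize_stimuli = TRUE`.
#' @param combine `"concatenate"` (default) pools all outputs before the
#'   RMS; `"average"` takes the mean per-stimulus RMS.
#' @param standardize_stimuli Z-score each spectrogram's bands before
#'   convolution (default `FALSE`: the caller supplies spectrograms on the
#'   fitting scale; the operation is then linear in the stimulus).
#' @return RMS scalar.
#' @export
speech_output_power <- function(gain, spectrograms,
                                combine = c("concatenate", "average"),
                                standardize_stimuli = FALSE) {
  combine <- match.arg(combine)
  if (inherits(gain, "strf_fit")) gain <- gain$gain
  gain <- as.matrix(gain)
  s <- stats::sd(gain)
  if (!is.finite(s) || s == 0)
    stop_invalid("degenerate (constant) STRF: z-score undefined")
  gz <- (gain - mean(gain)) / s
  if (!is.list(spectrograms) || inherits(spectrograms, "aud_spectrogram"))
    spectrograms <- list(spectrograms)
  outs <- lapply(spectrograms, function(S)
    predict_hfb(gz, S, standardize = standardize_stimuli))
  if (combine == "concatenate") rms(unlist(outs)) else
    mean(vapply(outs, rms, numeric(1)))
}

#' Generalization of MIDDLE-condition coefficients to filtered speech
#'
#' Predicts the HFB response in a filtered condition using the eSTRF fit on
#' unfiltered (MIDDLE) speech and scores the prediction with R^2 per trial.
#' Prediction and observation are both z-scored before scoring: the MIDDLE
#' model's output lives on the unfiltered-condition standardized scale, so
#' only the shape of the prediction is held against the filtered-condition
#' response.
#'
#' @param fit_middle `strf_fit` (or gain matrix) estimated on unfiltered
#'   speech.
#' @param S_trials List of filtered-condition stimulus matrices.
#' @param r_trials List of observed HFB vectors, matched to `S_trials`.
#' @return Mean R^2 across trials (with per-trial values as attribute
#'   `"per_trial"`).
#' @export
generalization_score <- function(fit_middle, S_trials, r_trials) {
  if (!is.list(S_trials)) S_trials <- list(S_trials)
  if (!is.list(r_trials)) r_trials <- list(r_trials)
  stopifnot(length(S_trials) == length(r_trials))
  zv <- function(x) (x - mean(x)) / max(stats::sd(x), .Machine$double.eps)
  per <- vapply(seq_along(S_trials), function(k) {
    pred <- predict_hfb(fit_middle, S_trials[[k]])
    score_r2(zv(pred), zv(as.numeric(r_trials[[k]])))
  }, numeric(1))
  out <- mean(per)
  attr(out, "per_trial") <- per
  out
}

#' Partial correlation of two tensors given a third
#'
#' Flattens the inputs, regresses `a` and `b` on `conditioned` (ordinary
#' least squares with an intercept), and correlates the residuals.
#'
#' @param a,b,conditioned Numeric tensors/vectors of equal length.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(a, b, conditioned) {
  a <- as.numeric(a); b <- as.numeric(b); cv <- as.numeric(conditioned)
  if (length(a) != length(b) || length(a) != length(cv))
    stop_invalid("all inputs must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_invalid("constant input: partial correlation undefined")
  res <- function(y) stats::lm.fit(cbind(1, cv), y)$residuals
  ra <- res(a); rb <- res(b)
  # an input fully explained by the conditioned variable has nothing left to
  # correlate: perfect residualization gives 0
  tol <- 1e-12 * max(stats::sd(a), stats::sd(b))
  if (stats::sd(ra) <= tol || stats::sd(rb) <= tol) return(0)
  stats::cor(ra, rb)
}

# z-scored eSTRF per the fitting convention: mean / s.d. across CV splits
strf_zmap <- function(fit) {
  if (inherits(fit, "strf_fit")) as.numeric(t(fit$tmap)) else
    as.numeric(t(as.matrix(fit)))
}

#' Per-electrode partial-correlation tuning-shift contrast
#'
#' The headline statistic: for every electrode,
#' `delta_rho = rho(AFTER, MIDDLE | BEFORE) - rho(BEFORE, MIDDLE | AFTER)`,
#' computed on the z-scored eSTRFs (coefficient mean / s.d. across jackknife
#' folds).  Positive values mean the AFTER tuning is closer to the
#' unfiltered-speech tuning once the shared BEFORE structure is removed.
#'
#' @param fits_by_condition Named list with `before`, `middle`, `after`
#'   elements, each a list of `strf_fit` per electrode.
#' @return Data frame with `electrode`, `rho_am_b`, `rho_bm_a`, `delta_rho`.
#' @export
tuning_shift_contrast <- function(fits_by_condition) {
  stopifnot(all(c("before", "middle", "after") %in%
                  names(fits_by_condition)))
  n_el <- length(fits_by_condition$before)
  rows <- lapply(seq_len(n_el), function(e) {
    a <- strf_zmap(fits_by_condition$after[[e]])
    b <- strf_zmap(fits_by_condition$before[[e]])
    m <- strf_zmap(fits_by_condition$middle[[e]])
    data.frame(electrode = e,
               rho_am_b = partial_correlation(a, m, b),
               rho_bm_a = partial_correlation(b, m, a),
               delta_rho = partial_correlation(a, m, b) -
                 partial_correlation(b, m, a))
  })
  do.call(rbind, rows)
}
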