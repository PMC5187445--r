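# Trial-to-trial response similarity between conditions.
#
# The similarity of the HFB response to two presentations of related stimuli
# is measured as multitaper magnitude-squared coherence, pooled over trials
# within a sliding window, jackknife-debiased over trials, and converted to a
# frequency-integrated information rate in bits/s:
#
#   MI = -integral log2(1 - gamma^2(f)) df
#
# (the normal, i.e. Gaussian-channel, mutual information of the coherence).
# This form is reconstructed from the standard coherence-information
# literature; it is exact for jointly Gaussian signals.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the eigenvectors of the classical symmetric tridiagonal
#' matrix commutation; tapers are unit-energy, ordered by concentration.
#'
#' @param n Window length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  w <- nw / n
  tt <- 0:(n - 1)
  md <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- diag(md)
  A[cbind(1:(n - 1), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1))] <- od
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    tap[, i] <- tap[, i] / sqrt(sum(tap[, i]^2))
    if (sum(tap[, i]) < 0) tap[, i] <- -tap[, i]
  }
  tap
}

# Tapered spectra of one window of one signal: returns array freq x taper x
# trial of complex FFT coefficients (positive frequencies, DC excluded).
tapered_fft <- function(X, tapers) {
  n <- ncol(X)
  n_keep <- floor(n / 2)
  out <- array(0i, c(n_keep, ncol(tapers), nrow(X)))
  Xc <- X - rowMeans(X)
  for (k in seq_len(ncol(tapers))) {
    F <- stats::mvfft(t(Xc) * tapers[, k])
    out[, k, ] <- F[2:(n_keep + 1), , drop = FALSE]
  }
  out
}

coherence_from_cross <- function(sxy, sxx, syy) {
  Mod(sxy)^2 / pmax(sxx * syy, .Machine$double.xmin)
}

#' Sliding-window multitaper coherence between paired trial sets
#'
#' For each window, tapered cross- and auto-spectra are pooled over trials
#' and tapers to give the magnitude-squared coherence `gamma^2(f)`.  A
#' leave-one-trial-out jackknife on the variance-stabilized transform
#' `atanh(sqrt(gamma^2))` debiases the estimate (debiased values can dip
#' below 0) and provides a standard error.  The coherence track is converted
#' to an information rate per window with [coherence_to_mi()].
#'
#' @param x_trials,y_trials Trial x time matrices of paired responses (same
#'   dimensions; trial k of `x` is compared with trial k of `y`).
#' @param rate Sample rate in Hz.
#' @param times Time stamps of columns in seconds (default starts at 0).
#' @param window_s Window length in seconds (default 0.4).
#' @param step_s Window step in seconds (default 0.2).
#' @param nw Multitaper time-bandwidth product (default 2, giving 3 tapers).
#' @return Object of class `coherence_track`: `windows` (centre times),
#'   `freqs`, `coherence` (window x freq debiased), `coherence_raw`,
#'   `jackknife_se` (on the atanh scale), and `mi` (bits/s per window).
#' @export
multitaper_coherence <- function(x_trials, y_trials, rate, times = NULL,
                                 window_s = 0.4, step_s = 0.2, nw = 2) {
  x_trials <- as.matrix(x_trials); y_trials <- as.matrix(y_trials)
  if (!all(dim(x_trials) == dim(y_trials)))
    stop_invalid("x_trials and y_trials must have identical dimensions")
  n_tr <- nrow(x_trials)
  if (n_tr < 5) warning("fewer than 5 trials; coherence estimate is weak")
  n_time <- ncol(x_trials)
  if (is.null(times)) times <- (seq_len(n_time) - 1) / rate
  n_win <- max(1L, as.integer(round(window_s * rate)))
  step <- max(1L, as.integer(round(step_s * rate)))
  starts <- seq(1L, n_time - n_win + 1L, by = step)
  tapers <- dpss_tapers(n_win, nw)
  n_keep <- floor(n_win / 2)
  freqs <- (1:n_keep) * rate / n_win

  coh_raw <- matrix(NA_real_, length(starts), n_keep)
  coh_deb <- matrix(NA_real_, length(starts), n_keep)
  jse <- matrix(NA_real_, length(starts), n_keep)
  clip_q <- function(g2) pmin(sqrt(pmax(g2, 0)), 1 - 1e-12)

  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + n_win - 1)
    Fx <- tapered_fft(x_trials[, idx, drop = FALSE], tapers)
    Fy <- tapered_fft(y_trials[, idx, drop = FALSE], tapers)
    # per-trial sums over tapers
    pxy <- apply(Fx * Conj(Fy), c(1, 3), sum)
    pxx <- apply(Mod(Fx)^2, c(1, 3), sum)
    pyy <- apply(Mod(Fy)^2, c(1, 3), sum)
    sxy <- rowSums(pxy); sxx <- rowSums(pxx); syy <- rowSums(pyy)
    g2 <- coherence_from_cross(sxy, sxx, syy)
    coh_raw[wi, ] <- g2
    z_all <- atanh(clip_q(g2))
    z_loo <- vapply(seq_len(n_tr), function(i) {
      atanh(clip_q(coherence_from_cross(sxy - pxy[, i], sxx - pxx[, i],
                                        syy - pyy[, i])))
    }, numeric(n_keep))
    z_bar <- rowMeans(z_loo)
    z_deb <- n_tr * z_all - (n_tr - 1) * z_bar
    q_deb <- tanh(z_deb)
    coh_deb[wi, ] <- sign(q_deb) * q_deb^2
    jse[wi, ] <- sqrt((n_tr - 1) / n_tr *
                        rowSums((z_loo - z_bar)^2))
  }
  centers <- times[starts] + (n_win - 1) / (2 * rate)
  track <- structure(list(
    windows = centers, freqs = freqs, coherence = coh_deb,
    coherence_raw = coh_raw, jackknife_se = jse, rate = rate,
    window_s = window_s, step_s = step_s, nw = nw, n_trials = n_tr),
    class = "coherence_track")
  track$mi <- coherence_to_mi(track)
  track
}

#' Convert a coherence spectrum to an information rate (bits/s)
#'
#' `MI = -integral log2(1 - gamma^2(f)) df`, integrated over the resolved
#' frequencies by the trapezoid rule; coherence is clipped to
#' `[0, 1 - 1e-6]` first.
#'
#' @param track A `coherence_track`, or a matrix of coherence values
#'   (window x freq) if `freqs` is supplied.
#' @param freqs Frequency axis in Hz (taken from `track` if absent).
#' @return Bits/s per window (vector).
#' @export
coherence_to_mi <- function(track, freqs = NULL) {
  if (inherits(track, "coherence_track")) {
    coh <- track$coherence
    freqs <- track$freqs
  } else {
    coh <- as.matrix(track)
  }
  coh <- pmin(pmax(coh, 0), 1 - 1e-6)
  integrand <- -log2(1 - coh)
  if (length(freqs) == 1) return(as.numeric(integrand * freqs))
  df <- diff(freqs)
  w <- c(df[1] / 2, (df[-1] + df[-length(df)]) / 2, df[length(df)] / 2)
  as.numeric(integrand %*% w)
}

#' Remove the across-trial mean response from every trial
#'
#' Subtracting each electrode's time-varying mean evoked response leaves only
#' the sentence-specific component, so subsequent coherence reflects shared
#' stimulus-specific structure rather than a global onset response.
#'
#' @param epochs Trial x time matrix (one electrode) or a trial x time x
#'   electrode array.
#' @return Same shape, with the across-trial mean trace removed.
#' @export
subtract_global_response <- function(epochs) {
  if (is.matrix(epochs)) {
    return(sweep(epochs, 2, colMeans(epochs)))
  }
  out <- epochs
  for (e in seq_len(dim(epochs)[3]))
    out[, , e] <- sweep(epochs[, , e], 2, colMeans(epochs[, , e]))
  out
}

#' Between-condition similarity contrast in bits/s
#'
#' For every electrode, computes the windowed MI track between the AFTER and
#' MIDDLE responses and between the BEFORE and MIDDLE responses, and returns
#' the post-stimulus mean difference
#' `delta = mean MI(AFTER, MIDDLE) - mean MI(BEFORE, MIDDLE)`, together with
#' window-group means for the pre-stimulus, early and late periods.
#'
#' @param epochs Named list with elements `before`, `middle`, `after`, each a
#'   trial x time x electrode array of paired epochs.
#' @param rate Sample rate (Hz).
#' @param times Time stamps of columns (s, relative to stimulus onset).
#' @param subtract_global Remove each electrode's mean evoked response first
#'   (default `TRUE`).
#' @param groups Window grouping for reporting, a named list of `c(lo, hi)`
#'   intervals in seconds.
#' @param ... Passed to [multitaper_coherence()].
#' @return A data frame with one row per electrode: `delta_bits` (mean over
#'   post-stimulus windows), plus `am_<group>` / `bm_<group>` columns of MI
#'   by window group and condition pair.
#' @export
condition_similarity_contrast <- function(epochs, rate, times,
                                          subtract_global = TRUE,
                                          groups = list(pre = c(-1, 0),
                                                        early = c(0, 1),
                                                        late = c(1, 2.5)),
                                          ...) {
  stopifnot(all(c("before", "middle", "after") %in% names(epochs)))
  n_el <- dim(epochs$before)[3]
  ep <- epochs
  if (subtract_global) ep <- lapply(epochs, subtract_global_response)
  rows <- lapply(seq_len(n_el), function(e) {
    am <- multitaper_coherence(ep$after[, , e], ep$middle[, , e], rate,
                               times = times, ...)
    bm <- multitaper_coherence(ep$before[, , e], ep$middle[, , e], rate,
                               times = times, ...)
    post <- am$windows >= 0
    out <- data.frame(electrode = e,
                      delta_bits = mean(am$mi[post]) - mean(bm$mi[post]))
    for (gname in names(groups)) {
      g <- groups[[gname]]
      sel <- am$windows >= g[1] & am$windows < g[2]
      out[[paste0("am_", gname)]] <- if (any(sel)) mean(am$mi[sel]) else NA
      out[[paste0("bm_", gname)]] <- if (any(sel)) mean(bm$mi[sel]) else NA
    }
    out
  })
  do.call(rbind, rows)
}
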