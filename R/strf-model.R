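# Ensemble spectrotemporal receptive field (eSTRF) estimation.
#
# The encoding model is linear: the HFB response of electrode n at time t is
# a weighted sum of the auditory spectrogram over frequency bands p and
# causal lags tau in [0, 400] ms,
#
#   r(t, n) = sum_tau sum_p g(tau, p, n) * S(t - tau, p) + noise,
#
# estimated by ridge regression on z-scored inputs/outputs with
# leave-one-trial-out jackknife cross-validation.  Per-fold coefficient
# estimates provide both held-out R^2 and coefficient t-values
# (mean / s.d. across folds); a single ridge penalty, the mode of the
# per-fold argmax distribution, is shared by all electrodes and conditions so
# that every model sees the same prior.

#' Default lag grid for eSTRF models
#'
#' @param rate Sample rate of the auditory spectrogram and HFB (Hz).
#' @param max_lag Maximum causal lag in seconds (default 0.4).
#' @return Lags in seconds, `0, 1/rate, ..., max_lag` inclusive.
#' @export
strf_lags <- function(rate = 50, max_lag = 0.4) seq(0, max_lag, by = 1 / rate)

#' Default ridge penalty grid
#'
#' Log-spaced from 1e-2 to 1e6, 17 points.
#' @return Numeric vector of penalties.
#' @export
strf_ridge_grid <- function() 10^seq(-2, 6, length.out = 17)

strf_vec <- function(g) as.numeric(t(g))
strf_unvec <- function(w, n_lag, n_band) t(matrix(w, n_band, n_lag))

#' Build the lag-expanded design matrix for one trial
#'
#' Columns are (lag, band) pairs in lag-major order: all bands at lag 0,
#' then all bands at one sample of lag, and so on.  Stimulus history before
#' the start of the trial is zero-padded, so rows never mix trials.
#'
#' @param S Time x band stimulus matrix (or `aud_spectrogram`).
#' @param n_lags Number of lag steps (21 for 0-400 ms at 50 Hz).
#' @return A `nrow(S) x (n_lags * ncol(S))` matrix.
#' @export
build_lagged_design <- function(S, n_lags) {
  if (inherits(S, "aud_spectrogram")) S <- S$values
  S <- as.matrix(S)
  if (n_lags < 1 || n_lags != round(n_lags))
    stop_invalid("n_lags must be a positive integer")
  n_t <- nrow(S); n_b <- ncol(S)
  X <- matrix(0, n_t, n_lags * n_b)
  for (l in seq_len(n_lags)) {
    X[l:n_t, ((l - 1) * n_b + 1):(l * n_b)] <- S[1:(n_t - l + 1), ,
                                                 drop = FALSE]
  }
  X
}

#' Ridge regression with a fixed penalty
#'
#' Minimizes `||y - X w||^2 + lambda ||w||^2` with no intercept; inputs are
#' expected to be centred (z-scored) beforehand.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param lambda Non-negative ridge penalty.
#' @return Coefficient vector.
#' @export
fit_ridge <- function(X, y, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop_invalid("lambda must be a single non-negative number")
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + lambda
  as.numeric(solve(XtX, crossprod(X, y)))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; negative values occur when predictions are worse
#' than the mean of the observations, as can happen on held-out data.
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return Scalar R^2.
#' @export
score_r2 <- function(predicted, actual) {
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Predict HFB from a fitted eSTRF
#'
#' Convolves the gain tensor with a stimulus spectrogram:
#' `r_hat(t) = sum_tau sum_p g(tau, p) S(t - tau, p)` on the standardized
#' scale.
#'
#' @param fit An `strf_fit` or a lag x band gain matrix.
#' @param S Time x band stimulus (or `aud_spectrogram`); standardized
#'   column-wise before convolution when `standardize = TRUE`.
#' @param standardize Z-score the stimulus columns first (default `TRUE`,
#'   matching the fitting convention).
#' @return Predicted trace, length `nrow(S)`.
#' @export
predict_hfb <- function(fit, S, standardize = TRUE) {
  g <- if (inherits(fit, "strf_fit")) fit$gain else as.matrix(fit)
  if (inherits(S, "aud_spectrogram")) S <- S$values
  S <- as.matrix(S)
  if (ncol(S) != ncol(g))
    stop_invalid("stimulus has %d bands but the eSTRF has %d",
                 ncol(S), ncol(g))
  if (standardize) {
    sds <- apply(S, 2, stats::sd)
    S <- sweep(sweep(S, 2, colMeans(S)), 2, pmax(sds, .Machine$double.eps),
               `/`)
  }
  as.numeric(build_lagged_design(S, nrow(g)) %*% strf_vec(g))
}

#' Pick the global ridge penalty as the mode of per-fold argmax penalties
#'
#' Ties are broken toward the larger penalty (more regularization).
#'
#' @param lambdas Vector of selected penalties (values from `grid`).
#' @param grid The discrete penalty grid searched.
#' @return A single penalty value.
#' @export
select_global_ridge <- function(lambdas, grid = sort(unique(lambdas))) {
  grid <- sort(grid)
  idx <- vapply(lambdas, function(l) which.min(abs(grid - l)), integer(1))
  counts <- tabulate(idx, nbins = length(grid))
  grid[max(which(counts == max(counts)))]
}

# Per-trial sufficient statistics for pooled standardized ridge fits
trial_stats <- function(X, Y) {
  list(XtX = crossprod(X), XtY = crossprod(X, Y), xsum = colSums(X),
       ysum = colSums(Y), y2sum = colSums(Y^2), x2sum = colSums(X^2),
       n = nrow(X))
}

#' Jackknifed ridge eSTRF fits for all electrodes of one condition
#'
#' Leave-one-trial-out cross-validation: for every held-out trial the model
#' is fit on the remaining trials over a penalty grid (inputs/outputs
#' z-scored with training-fold statistics), held-out R^2 recorded per
#' penalty.  The design-matrix factorization is shared across electrodes,
#' which makes fitting hundreds of electrodes on the same stimuli cheap.
#'
#' @param S_trials List of time x band stimulus matrices, one per trial.
#' @param R_trials List of time x electrode response matrices, one per trial
#'   (row counts matching `S_trials`).
#' @param n_lags Number of causal lags (default 21: 0-400 ms at 50 Hz).
#' @param ridge_grid Penalty grid to search.
#' @param ridge Optional fixed penalty; when given, the grid is still scored
#'   but the reported fit uses this penalty (the "global" re-fit).
#' @param keep_solvers Keep per-fold factorizations (as an attribute) so
#'   [refit_condition_strfs()] can re-extract coefficients at another
#'   penalty without re-fitting; only available with `ridge = NULL`.
#' @return List of `strf_fit` objects, one per electrode, each with elements
#'   `gain` (mean of per-fold standardized coefficients, lag x band),
#'   `gain_native` (coefficients mapped back to the raw stimulus/response
#'   scale), `fold_gains`, `tmap` (mean/s.d. across folds), `ridge`,
#'   `fold_r2`, `ci_lower_r2` (0.5th percentile of `fold_r2`), `fold_argmax`
#'   (per-fold best penalty), and `r2_grid` (fold x penalty held-out R^2).
#' @export
fit_condition_strfs <- function(S_trials, R_trials, n_lags = 21,
                                ridge_grid = strf_ridge_grid(),
                                ridge = NULL, keep_solvers = FALSE) {
  n_trials <- length(S_trials)
  if (n_trials < 2) stop_invalid("jackknife needs at least 2 trials")
  if (length(R_trials) != n_trials)
    stop_invalid("S_trials and R_trials must have the same length")
  S_trials <- lapply(S_trials, function(S)
    if (inherits(S, "aud_spectrogram")) S$values else as.matrix(S))
  R_trials <- lapply(R_trials, function(R) {
    R <- as.matrix(R); R
  })
  n_el <- ncol(R_trials[[1]])
  n_band <- ncol(S_trials[[1]])
  p <- n_lags * n_band
  if (!is.null(ridge)) {
    if (ridge < 0) stop_invalid("ridge must be non-negative")
    if (!any(ridge_grid == ridge)) ridge_grid <- sort(c(ridge_grid, ridge))
  }
  designs <- lapply(S_trials, build_lagged_design, n_lags = n_lags)
  stats_list <- Map(trial_stats, designs, R_trials)
  n_grid <- length(ridge_grid)
  min_fold_n <- min(vapply(stats_list, `[[`, numeric(1), "n")) *
    (n_trials - 1)
  if (min_fold_n < 0.2 * p)
    warning(sprintf("training folds have only %d samples for %d parameters",
                    min_fold_n, p))

  r2_all <- array(NA_real_, c(n_trials, n_grid, n_el))
  W_fold <- vector("list", n_trials)     # p x n_el coefficients at `ridge`
  Wn_fold <- vector("list", n_trials)    # native-scale version
  ridge_idx <- if (!is.null(ridge)) which(ridge_grid == ridge) else
    NA_integer_

  for (j in seq_len(n_trials)) {
    tr <- setdiff(seq_len(n_trials), j)
    n_tr <- sum(vapply(stats_list[tr], `[[`, numeric(1), "n"))
    xsum <- Reduce(`+`, lapply(stats_list[tr], `[[`, "xsum"))
    x2sum <- Reduce(`+`, lapply(stats_list[tr], `[[`, "x2sum"))
    ysum <- Reduce(`+`, lapply(stats_list[tr], `[[`, "ysum"))
    y2sum <- Reduce(`+`, lapply(stats_list[tr], `[[`, "y2sum"))
    mu <- xsum / n_tr
    sx <- sqrt(pmax(x2sum / n_tr - mu^2, 0))
    sx <- pmax(sx, .Machine$double.eps)
    ybar <- ysum / n_tr
    sy <- sqrt(pmax(y2sum / n_tr - ybar^2, 0))
    sy <- pmax(sy, .Machine$double.eps)
    XtX <- Reduce(`+`, lapply(stats_list[tr], `[[`, "XtX"))
    XtY <- Reduce(`+`, lapply(stats_list[tr], `[[`, "XtY"))
    XtX_std <- (XtX - n_tr * tcrossprod(mu)) / tcrossprod(sx)
    XtY_std <- sweep((XtY - outer(xsum, ybar)) / sx, 2, sy, `/`)
    eg <- eigen(XtX_std, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    A <- crossprod(eg$vectors, XtY_std)          # p x n_el
    Xte <- sweep(sweep(designs[[j]], 2, mu), 2, sx, `/`)
    Yte <- sweep(sweep(R_trials[[j]], 2, ybar), 2, sy, `/`)
    for (gi in seq_len(n_grid)) {
      W <- eg$vectors %*% (A / (d + ridge_grid[gi]))
      pred <- Xte %*% W
      for (e in seq_len(n_el))
        r2_all[j, gi, e] <- score_r2(pred[, e], Yte[, e])
      if (!is.na(ridge_idx) && gi == ridge_idx) {
        W_fold[[j]] <- W
        Wn_fold[[j]] <- sweep(W / sx, 2, sy, `*`)
      }
    }
    if (is.na(ridge_idx)) {
      # keep what is needed to re-extract coefficients at any grid penalty
      W_fold[[j]] <- list(V = eg$vectors, d = d, A = A, sx = sx, sy = sy)
    }
  }

  argmax_idx <- apply(r2_all, c(1, 3), which.max)   # trials x electrodes
  solvers <- NULL
  if (is.null(ridge)) {
    if (keep_solvers) solvers <- W_fold
    ridge <- select_global_ridge(ridge_grid[as.vector(argmax_idx)],
                                 ridge_grid)
    ridge_idx <- which(ridge_grid == ridge)
    for (j in seq_len(n_trials)) {
      st <- if (keep_solvers) solvers[[j]] else W_fold[[j]]
      W <- st$V %*% (st$A / (st$d + ridge))
      Wn_fold[[j]] <- sweep(W / st$sx, 2, st$sy, `*`)
      W_fold[[j]] <- W
    }
  }

  fits <- lapply(seq_len(n_el), function(e) {
    fg <- vapply(W_fold, function(W) W[, e], numeric(p))    # p x n_folds
    fgn <- vapply(Wn_fold, function(W) W[, e], numeric(p))
    gmean <- rowMeans(fg)
    gsd <- apply(fg, 1, stats::sd)
    tmap <- ifelse(gsd > 0, gmean / gsd, 0)
    fold_r2 <- r2_all[, ridge_idx, e]
    structure(list(
      gain = strf_unvec(gmean, n_lags, n_band),
      gain_native = strf_unvec(rowMeans(fgn), n_lags, n_band),
      fold_gains = aperm(array(fg, c(n_band, n_lags, n_trials)), c(2, 1, 3)),
      tmap = strf_unvec(tmap, n_lags, n_band),
      ridge = ridge,
      fold_r2 = fold_r2,
      ci_lower_r2 = as.numeric(stats::quantile(fold_r2, 0.005,
                                               na.rm = TRUE)),
      fold_argmax = ridge_grid[argmax_idx[, e]],
      r2_grid = r2_all[, , e],
      n_lags = n_lags, n_bands = n_band
    ), class = "strf_fit")
  })
  if (!is.null(solvers)) {
    attr(fits, "solvers") <- solvers
    attr(fits, "ridge_grid") <- ridge_grid
    attr(fits, "r2_all") <- r2_all
  }
  fits
}

# Re-extract per-fold coefficients at a different grid penalty using the
# factorizations kept by fit_condition_strfs(keep_solvers = TRUE).
refit_condition_strfs <- function(fits, ridge) {
  solvers <- attr(fits, "solvers")
  ridge_grid <- attr(fits, "ridge_grid")
  r2_all <- attr(fits, "r2_all")
  if (is.null(solvers)) stop_invalid("fits were not kept with solvers")
  ridge_idx <- which.min(abs(ridge_grid - ridge))
  ridge <- ridge_grid[ridge_idx]
  n_trials <- length(solvers)
  n_el <- length(fits)
  p <- nrow(solvers[[1]]$A)
  W_fold <- vector("list", n_trials)
  Wn_fold <- vector("list", n_trials)
  for (j in seq_len(n_trials)) {
    st <- solvers[[j]]
    W <- st$V %*% (st$A / (st$d + ridge))
    W_fold[[j]] <- W
    Wn_fold[[j]] <- sweep(W / st$sx, 2, st$sy, `*`)
  }
  out <- lapply(seq_len(n_el), function(e) {
    fit <- fits[[e]]
    fg <- vapply(W_fold, function(W) W[, e], numeric(p))
    fgn <- vapply(Wn_fold, function(W) W[, e], numeric(p))
    gmean <- rowMeans(fg)
    gsd <- apply(fg, 1, stats::sd)
    fold_r2 <- r2_all[, ridge_idx, e]
    fit$gain <- strf_unvec(gmean, fit$n_lags, fit$n_bands)
    fit$gain_native <- strf_unvec(rowMeans(fgn), fit$n_lags, fit$n_bands)
    fit$fold_gains <- aperm(array(fg, c(fit$n_bands, fit$n_lags, n_trials)),
                            c(2, 1, 3))
    fit$tmap <- strf_unvec(ifelse(gsd > 0, gmean / gsd, 0),
                           fit$n_lags, fit$n_bands)
    fit$ridge <- ridge
    fit$fold_r2 <- fold_r2
    fit$ci_lower_r2 <- as.numeric(stats::quantile(fold_r2, 0.005,
                                                  na.rm = TRUE))
    fit
  })
  out
}

#' Jackknifed ridge eSTRF fit for a single electrode
#'
#' Convenience wrapper around [fit_condition_strfs()] for one electrode.
#'
#' @param trials List of trials, each a list with elements `S` (time x band
#'   stimulus) and `r` (response vector).
#' @inheritParams fit_condition_strfs
#' @return An `strf_fit` (see [fit_condition_strfs()]).
#' @export
fit_strf_jackknife <- function(trials, n_lags = 21,
                               ridge_grid = strf_ridge_grid(),
                               ridge = NULL) {
  S_trials <- lapply(trials, `[[`, "S")
  R_trials <- lapply(trials, function(tr) matrix(tr$r, ncol = 1))
  fit_condition_strfs(S_trials, R_trials, n_lags = n_lags,
                      ridge_grid = ridge_grid, ridge = ridge)[[1]]
}

#' Is an electrode spectrotemporally responsive (STRF-R)?
#'
#' An electrode is STRF-R when the lower bound of the 99% two-sided interval
#' of held-out R^2 across jackknife folds (the 0.5th percentile) is strictly
#' greater than 0.
#'
#' @param fit An `strf_fit`.
#' @return Logical.
#' @export
select_strf_responsive <- function(fit) {
  stopifnot(inherits(fit, "strf_fit"))
  isTRUE(fit$ci_lower_r2 > 0)
}

#' @export
print.strf_fit <- function(x, ...) {
  cat(sprintf(
    "eSTRF fit: %d lags x %d bands, %d folds, ridge = %g\n  mean held-out R^2 = %.3f (0.5th pct %.3f)%s\n",
    x$n_lags, x$n_bands, length(x$fold_r2), x$ridge, mean(x$fold_r2),
    x$ci_lower_r2,
    if (select_strf_responsive(x)) " [STRF-R]" else ""))
  invisible(x)
}
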