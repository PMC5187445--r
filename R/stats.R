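# Resampling inference for paired condition contrasts.
#
# All between-condition comparisons are paired per electrode, so the null is
# simulated by randomly flipping the sign of each electrode's difference.
# P-values use the +1 convention (the observed statistic counts as one
# permutation), so they are never exactly 0.

#' Sign-flip permutation test for paired differences
#'
#' @param differences Per-electrode condition differences.
#' @param n_perm Number of random sign assignments (default 10000).
#' @param seed RNG seed.
#' @return Object of class `perm_result`: `observed` (mean difference),
#'   `null_distribution`, `p_two_sided`, `n_permutations`, `seed`.
#' @export
signflip_permutation_test <- function(differences, n_perm = 10000, seed = 1) {
  d <- as.numeric(differences)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 5) warning("fewer than 5 paired differences; test is weak")
  observed <- mean(d)
  if (all(d == 0)) {
    return(structure(list(observed = 0,
                          null_distribution = numeric(n_perm),
                          p_two_sided = 1, n_permutations = n_perm,
                          seed = seed), class = "perm_result"))
  }
  null_means <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    as.numeric(signs %*% d) / n
  })
  p <- (1 + sum(abs(null_means) >= abs(observed) - 1e-12)) / (n_perm + 1)
  structure(list(observed = observed, null_distribution = null_means,
                 p_two_sided = p, n_permutations = n_perm, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("sign-flip permutation test: observed mean = %.4g, p = %.4g (%d permutations)\n",
              x$observed, x$p_two_sided, x$n_permutations))
  invisible(x)
}

# t statistics across rows (electrodes) for every column, given optional
# row-wise sign flips encoded as a perm x electrode matrix.  Sign flips leave
# each entry's square unchanged, so the second moment is shared and only the
# mean depends on the flips.
signed_tstats <- function(D, signs) {
  n <- nrow(D)
  m2 <- colMeans(D^2)
  means <- (signs %*% D) / n
  vars <- sweep(-means^2, 2, m2, `+`) * n / (n - 1)
  means / sqrt(pmax(vars, .Machine$double.xmin) / n)
}

cluster_masses <- function(tvals, thresh) {
  above <- abs(tvals) > thresh
  if (!any(above)) return(list(mass = numeric(0), start = integer(0),
                               end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  mass <- vapply(keep, function(k) sum(tvals[starts[k]:ends[k]]), numeric(1))
  list(mass = mass, start = starts[keep], end = ends[keep])
}

#' Cluster-based permutation test over time
#'
#' One-sample t statistics across electrodes are computed at every time
#' point; contiguous runs where `|t|` exceeds the two-sided critical value at
#' `cluster_alpha` form clusters, scored by the sum of t within the cluster
#' (cluster mass).  The null distribution is the maximum absolute cluster
#' mass under electrode-wise sign flips, which corrects for multiple
#' comparisons across time.
#'
#' @param D Electrode x time matrix of per-electrode difference time series.
#' @param n_perm Number of sign-flip permutations.
#' @param cluster_alpha Two-sided alpha for the cluster-forming threshold.
#' @param seed RNG seed.
#' @return Object of class `cluster_perm_result`: data frame `clusters` with
#'   `start`, `end` (column indices), `mass` and `p`, plus the per-timepoint
#'   `tvals`, the `null_max_mass` distribution and bookkeeping fields.  With
#'   no supra-threshold cluster, `clusters` has zero rows.
#' @export
cluster_permutation_test <- function(D, n_perm = 1000, cluster_alpha = 0.05,
                                     seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 5) warning("fewer than 5 electrodes; cluster test is weak")
  thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tvals <- as.numeric(signed_tstats(D, matrix(1, 1, n)))
  obs <- cluster_masses(tvals, thresh)
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    tperm <- signed_tstats(D, signs)
    vapply(seq_len(n_perm), function(i) {
      cm <- cluster_masses(tperm[i, ], thresh)
      if (length(cm$mass)) max(abs(cm$mass)) else 0
    }, numeric(1))
  })
  p <- vapply(obs$mass, function(m)
    (1 + sum(null_max >= abs(m) - 1e-12)) / (n_perm + 1), numeric(1))
  structure(list(
    clusters = data.frame(start = obs$start, end = obs$end, mass = obs$mass,
                          p = p),
    tvals = tvals, threshold = thresh, null_max_mass = null_max,
    n_permutations = n_perm, seed = seed), class = "cluster_perm_result")
}

#' @export
print.cluster_perm_result <- function(x, ...) {
  if (nrow(x$clusters) == 0) {
    cat("cluster permutation test: no supra-threshold clusters\n")
  } else {
    cat(sprintf("cluster permutation test: %d cluster(s), min p = %.4g\n",
                nrow(x$clusters), min(x$clusters$p)))
  }
  invisible(x)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Per-trial values.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.99).
#' @param seed RNG seed.
#' @return Named vector `c(lower, upper)`: the `(1-level)/2` and
#'   `1-(1-level)/2` percentiles of the resampled mean.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.99, seed = 1) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2) return(c(lower = x[1], upper = x[1]))
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    rowMeans(matrix(x[idx], n_boot, n))
  })
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}
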