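test_that("MTF of analytic filters has the expected structure", {
  lags <- strf_lags()
  bands <- strfshift:::erb_centers(32)
  lf <- seq(log2(min(bands)), log2(max(bands)), length.out = 32)
  # delta-function STRF on an already log-spaced band grid: flat MTF
  d <- matrix(0, 21, 32); d[1, 1] <- 1
  md <- strf_mtf(d, lags, 2^lf)
  expect_lt(diff(range(md$amplitude)) / mean(md$amplitude), 1e-6)

  # separable Gabor on the (uniform log-frequency) grid: peak at its
  # temporal and spectral carrier frequencies
  wt0 <- 6                          # Hz
  wf0 <- 1 / (4 * (lf[2] - lf[1]))  # cycles/octave, 1 cycle per 4 bins
  gt <- exp(-((lags - 0.2) / 0.08)^2) * cos(2 * pi * wt0 * (lags - 0.2))
  gf <- exp(-((lf - lf[16]) / 0.8)^2) * cos(2 * pi * wf0 * (lf - lf[16]))
  g <- outer(gt, gf)
  m <- strf_mtf(g, lags, 2^lf)     # band centres already log-spaced
  pk <- which(m$amplitude == max(m$amplitude), arr.ind = TRUE)[1, ]
  expect_lt(abs(abs(m$wt[pk[1]]) - wt0), diff(m$wt[1:2]) + 1e-9)
  expect_lt(abs(m$wf[pk[2]] - wf0), diff(m$wf[1:2]) + 1e-9)

  # time reversal mirrors the signed-wt axis: the peak flips sign
  m_rev <- strf_mtf(g[21:1, ], lags, 2^lf)
  pk_rev <- which(m_rev$amplitude == max(m_rev$amplitude),
                  arr.ind = TRUE)[1, ]
  expect_lt(abs(m_rev$wt[pk_rev[1]] + m$wt[pk[1]]), diff(m$wt[1:2]) + 1e-9)
  expect_equal(m_rev$wf[pk_rev[2]], m$wf[pk[2]])
})

test_that("output power ranks stimulus-matched filters above random ones", {
  set.seed(3)
  S <- smooth_stimulus(400, 16, seed = 10)
  Sz <- scale(S)
  # matched filter: time-reversed stimulus snippet as the gain
  seg <- Sz[101:110, ]
  matched <- seg[10:1, ]
  p_matched <- speech_output_power(matched, Sz)
  beats <- vapply(1:100, function(i) {
    rnd <- matrix(sample(as.numeric(matched)), nrow(matched))
    p_matched > speech_output_power(rnd, Sz)
  }, logical(1))
  expect_gte(mean(beats), 0.95)
  # linearity: doubling the stimulus doubles the RMS
  g <- test_gabor(4)[1:10, 1:16]
  expect_equal(speech_output_power(g, 2 * Sz),
               2 * speech_output_power(g, Sz), tolerance = 1e-10)
  expect_error(speech_output_power(matrix(0, 5, 16), Sz), "degenerate")
})

test_that("generalization score is 1 for perfect prediction", {
  S <- smooth_stimulus(200, 32, seed = 2)
  g <- test_gabor(5)
  r <- predict_hfb(g, S)
  expect_equal(as.numeric(generalization_score(g, S, r)), 1,
               tolerance = 1e-9)
})

test_that("partial correlation matches the three-variable closed form exactly", {
  # construct vectors with exact sample correlations via Gram-Schmidt
  n <- 400
  set.seed(7)
  raw <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  basis <- qr.Q(qr(raw))   # orthonormal and zero-mean
  e1 <- basis[, 1]; e2 <- basis[, 2]; e3 <- basis[, 3]
  r_ab <- 0.6; r_ac <- 0.5; r_bc <- 0.5
  a <- e1
  b <- r_ab * e1 + sqrt(1 - r_ab^2) * e2
  lam2 <- (r_bc - r_ab * r_ac) / sqrt(1 - r_ab^2)
  cvec <- r_ac * e1 + lam2 * e2 + sqrt(1 - r_ac^2 - lam2^2) * e3
  expected <- (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  expect_lt(abs(partial_correlation(a, b, cvec) - expected), 1e-10)
  expect_equal(expected, 0.46667, tolerance = 1e-4)

  # a == b with an orthogonal conditioned variable: 1
  expect_equal(partial_correlation(e1, e1, e2), 1, tolerance = 1e-10)
  # a == conditioned: perfect residualization gives 0
  expect_equal(partial_correlation(cvec, b, cvec), 0)
  expect_error(partial_correlation(rep(1, n), b, cvec), "constant")
})

test_that("tuning shift contrast is antisymmetric and order-insensitive", {
  set.seed(9)
  mk_fit <- function(seed) {
    g <- test_gabor(seed)
    structure(list(tmap = g, gain = g, n_lags = 21, n_bands = 32),
              class = "strf_fit")
  }
  fits <- list(before = list(mk_fit(1), mk_fit(2)),
               middle = list(mk_fit(3), mk_fit(4)),
               after = list(mk_fit(5), mk_fit(6)))
  tab <- tuning_shift_contrast(fits)
  swapped <- tuning_shift_contrast(list(before = fits$after,
                                        middle = fits$middle,
                                        after = fits$before))
  expect_equal(swapped$delta_rho, -tab$delta_rho, tolerance = 1e-12)
  # vectorization order is irrelevant: permuting (lag, band) entries of all
  # tensors consistently leaves the correlations unchanged
  perm <- sample(21 * 32)
  fits_p <- lapply(fits, function(fl) lapply(fl, function(f) {
    f$tmap <- matrix(as.numeric(t(f$tmap))[perm], 21, 32, byrow = TRUE)
    f
  }))
  expect_equal(tuning_shift_contrast(fits_p)$delta_rho, tab$delta_rho,
               tolerance = 1e-12)
})
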