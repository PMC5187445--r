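test_that("coherence of identical, scaled and delayed signals is maximal", {
  set.seed(1)
  x <- matrix(rnorm(20 * 100), 20, 100)
  tr <- multitaper_coherence(x, x, rate = 100, window_s = 0.4,
                             step_s = 0.2)
  expect_true(all(abs(tr$coherence_raw - 1) < 1e-6))
  # amplitude scaling changes nothing
  tr_sc <- multitaper_coherence(x, 3.7 * x, rate = 100)
  expect_true(all(abs(tr_sc$coherence_raw - 1) < 1e-6))
  expect_error(multitaper_coherence(x, x[, 1:50], rate = 100),
               "identical dimensions")
})

test_that("debiased coherence is near zero for independent signals", {
  set.seed(2)
  means <- replicate(25, {
    x <- matrix(rnorm(20 * 40), 20, 40)
    y <- matrix(rnorm(20 * 40), 20, 40)
    tr <- multitaper_coherence(x, y, rate = 100, window_s = 0.4,
                               step_s = 0.4)
    mean(tr$coherence)
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("additive noise follows the gamma^2 = s/(1+s) law and MI matches", {
  set.seed(3)
  s <- 1.5  # per-frequency linear SNR
  reps <- replicate(12, {
    x <- matrix(rnorm(24 * 40), 24, 40)
    y <- x + matrix(rnorm(24 * 40, sd = sqrt(1 / s)), 24, 40)
    tr <- multitaper_coherence(x, y, rate = 100, window_s = 0.4,
                               step_s = 0.4)
    c(mean(tr$coherence), mean(tr$mi))
  })
  g2_expect <- s / (1 + s)
  expect_lt(abs(mean(reps[1, ]) - g2_expect), 0.06)
  # MI of a flat gamma^2 over the resolved band (2.5-50 Hz)
  mi_expect <- -log2(1 - g2_expect) * (50 - 2.5)
  expect_lt(abs(mean(reps[2, ]) / mi_expect - 1), 0.2)
})

test_that("MI conversion is exact for constant coherence and additive over bands", {
  freqs <- seq(0, 10, by = 0.5)
  expect_equal(coherence_to_mi(matrix(0, 1, length(freqs)), freqs = freqs),
               0)
  mi_half <- coherence_to_mi(matrix(0.5, 1, length(freqs)), freqs = freqs)
  expect_equal(mi_half, 10, tolerance = 1e-6)
  # additivity: two disjoint bands sum to the full integral
  g <- matrix(runif(21), 1, 21)
  lo <- 1:11; hi <- 11:21
  expect_equal(coherence_to_mi(g[, lo, drop = FALSE], freqs = freqs[lo]) +
                 coherence_to_mi(g[, hi, drop = FALSE],
                                 freqs = freqs[hi]),
               coherence_to_mi(g, freqs = freqs))
})

test_that("global response subtraction removes shared evoked structure", {
  set.seed(4)
  ep <- matrix(rnorm(15 * 60), 15, 60)
  out <- subtract_global_response(ep)
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # identical trials become exactly zero
  same <- matrix(rep(rnorm(60), each = 15), 15, 60)
  expect_true(all(subtract_global_response(same) == 0))
  # common evoked component + sentence-specific part: after subtraction the
  # coherence reflects only the sentence-specific channel
  common <- sin(2 * pi * 3 * (1:80) / 100) * 4
  x <- t(replicate(20, common + rnorm(80, sd = 1)))
  y <- t(replicate(20, common + rnorm(80, sd = 1)))
  raw <- multitaper_coherence(x, y, rate = 100, window_s = 0.4,
                              step_s = 0.4)
  sub <- multitaper_coherence(subtract_global_response(x),
                              subtract_global_response(y), rate = 100,
                              window_s = 0.4, step_s = 0.4)
  i3 <- which.min(abs(raw$freqs - 2.5))
  expect_gt(mean(raw$coherence[, i3]), 0.4)
  expect_lt(mean(abs(sub$coherence[, i3])), 0.1)
})

test_that("condition similarity contrast is antisymmetric under label swap", {
  set.seed(6)
  n_tr <- 8; n_t <- 150; n_el <- 2
  mk <- function() array(rnorm(n_tr * n_t * n_el), c(n_tr, n_t, n_el))
  base <- array(rnorm(n_tr * n_t * n_el), c(n_tr, n_t, n_el))
  epochs <- list(before = mk(), middle = base, after = base + 0.5 * mk())
  times <- seq(-0.5, by = 0.02, length.out = n_t)
  tab <- condition_similarity_contrast(epochs, rate = 50, times = times)
  swapped <- condition_similarity_contrast(
    list(before = epochs$after, middle = epochs$middle,
         after = epochs$before), rate = 50, times = times)
  expect_equal(swapped$delta_bits, -tab$delta_bits, tolerance = 1e-10)
  expect_equal(names(tab)[1:2], c("electrode", "delta_bits"))
})
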