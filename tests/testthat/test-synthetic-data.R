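test_that("speech-like sounds are deterministic, normalized and speech-concentrated", {
  x1 <- generate_speech_like_sound(2, 16000, seed = 1)
  x2 <- generate_speech_like_sound(2, 16000, seed = 1)
  expect_identical(x1, x2)
  expect_equal(length(x1), 2 * 16000)
  expect_equal(max(abs(x1)), 0.9, tolerance = 1e-12)
  expect_error(generate_speech_like_sound(0.3, 16000), "0.5")
  expect_error(generate_speech_like_sound(-1, 16000), "positive")

  # modulation power concentrates at low temporal/spectral modulations
  for (sd in c(1, 3)) {
    x <- generate_speech_like_sound(2, 16000, seed = sd)
    m <- compute_mps(compute_spectrogram(x, 16000))
    A2 <- m$amplitude^2
    A2[which(m$wt == 0), which(m$wf == 0)] <- 0
    frac <- sum(A2[abs(m$wt) < 10, m$wf < 3]) / sum(A2)
    expect_gt(frac, 0.7)
  }
})

test_that("ground-truth STRFs obey the lambda interpolation exactly", {
  cfg0 <- synthetic_config(n_trials = 2, n_electrodes = 4, shift_lambda = 0)
  tr0 <- generate_ground_truth_strfs(cfg0)
  expect_identical(tr0$strf_after, tr0$strf_before)
  cfg1 <- synthetic_config(n_trials = 2, n_electrodes = 4, shift_lambda = 1)
  tr1 <- generate_ground_truth_strfs(cfg1)
  expect_identical(tr1$strf_after, tr1$strf_middle)
  # standardization
  for (e in 1:4) {
    expect_lt(abs(mean(tr1$strf_before[, , e])), 1e-12)
    expect_equal(sd(tr1$strf_before[, , e]), 1, tolerance = 1e-12)
  }
  # half shift: partial correlation of (after, middle | before) positive
  cfg5 <- synthetic_config(n_trials = 2, n_electrodes = 6,
                           shift_lambda = 0.5)
  tr5 <- generate_ground_truth_strfs(cfg5)
  for (e in 1:6) {
    expect_gt(partial_correlation(tr5$strf_after[, , e],
                                  tr5$strf_middle[, , e],
                                  tr5$strf_before[, , e]), 0)
  }
})

test_that("simulated HFB is the causal convolution plus calibrated noise", {
  S <- smooth_stimulus(300, 32, seed = 4)
  # identity filter: one-hot gain reproduces the band series
  g1 <- matrix(0, 21, 32); g1[1, 7] <- 1
  expect_equal(simulate_hfb(g1, S, snr = Inf), S[, 7])
  # causality/time invariance: shifting the stimulus shifts the output
  g <- test_gabor(2)
  Sshift <- rbind(0, S[-nrow(S), ])
  r <- simulate_hfb(g, S, snr = Inf)
  rs <- simulate_hfb(g, Sshift, snr = Inf)
  expect_equal(rs[-1], r[-length(r)], tolerance = 1e-12)
  # superposition in the noiseless limit
  S2 <- smooth_stimulus(300, 32, seed = 5)
  expect_equal(simulate_hfb(g, S + S2, snr = Inf),
               simulate_hfb(g, S, snr = Inf) +
                 simulate_hfb(g, S2, snr = Inf), tolerance = 1e-9)
  # snr calibration within 10% on a long simulation
  Slong <- smooth_stimulus(3000, 32, seed = 6)
  sig <- simulate_hfb(g, Slong, snr = Inf)
  noisy <- simulate_hfb(g, Slong, snr = 4, seed = 9)
  snr_emp <- var(sig) / var(noisy - sig)
  expect_lt(abs(snr_emp / 4 - 1), 0.1)
  # AR(1) noise is calibrated too
  noisy_ar <- simulate_hfb(g, Slong, snr = 4, seed = 9,
                           noise_model = "ar1")
  expect_lt(abs(var(sig) / var(noisy_ar - sig) / 4 - 1), 0.15)
  expect_error(simulate_hfb(g, S[, 1:10], snr = 4), "band axis mismatch")
})

test_that("experiment generation is deterministic with the task's structure", {
  cfg <- tiny_cfg()
  ts1 <- tiny_experiment()
  # 3 conditions x 3 trials of stimulus presentations
  expect_equal(length(ts1$hfb), 3)
  expect_equal(dim(ts1$hfb$before),
               c(cfg$n_electrodes, dim(ts1$spec$before)[1], cfg$n_trials))
  # BEFORE and AFTER audio are bit-identical within a trial, and the same
  # spectrograms are used
  expect_identical(ts1$spec$before, ts1$spec$after)
  # no sound reused across trials
  expect_false(identical(ts1$audio[[1]]$unfiltered,
                         ts1$audio[[2]]$unfiltered))
  # determinism: regenerating with the same config matches bit for bit
  ts2 <- generate_experiment(cfg)
  expect_identical(ts1$hfb, ts2$hfb)
  expect_identical(ts1$audio, ts2$audio)
  # responses differ between conditions (different truths and stimuli)
  expect_false(identical(ts1$hfb$before, ts1$hfb$after))
})
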