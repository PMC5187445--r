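test_that("spectrogram of stationary and modulated tones behaves analytically", {
  rate <- 16000
  t <- (0:(1.5 * rate - 1)) / rate
  tone <- sin(2 * pi * 1000 * t)
  sp <- compute_spectrogram(tone, rate)
  ridge_bin <- which.min(abs(sp$freqs - 1000))
  # ridge at the bin nearest 1 kHz, constant over time within 1 dB
  interior <- seq(50, nrow(sp$values) - 50)
  expect_true(all(apply(sp$values[interior, ], 1, which.max) == ridge_bin))
  expect_lt(diff(range(sp$values[interior, ridge_bin])), 1)

  # silence clips to the floor everywhere
  sil <- compute_spectrogram(numeric(4000), rate)
  expect_true(all(sil$values == -sil$floor_db))

  # 4 Hz AM: the ridge amplitude oscillates at 4.0 +/- 0.2 Hz
  am <- am_tone(dur = 2, fm = 4)
  spa <- compute_spectrogram(am, rate)
  ridge <- spa$values[, which.min(abs(spa$freqs - 1000))]
  ridge <- ridge - mean(ridge)
  spec <- Mod(fft(ridge))[2:(length(ridge) %/% 2)]
  f_axis <- (1:(length(ridge) %/% 2 - 1)) / (length(ridge) * spa$time_step)
  expect_lt(abs(f_axis[which.max(spec)] - 4), 0.2)

  expect_error(compute_spectrogram(numeric(10), rate), "too short")
})

test_that("MPS has analytic peaks and satisfies Parseval exactly", {
  rate <- 16000
  spa <- compute_spectrogram(am_tone(dur = 2, fm = 4), rate)
  m <- compute_mps(spa)
  # Parseval: total transform power equals centred spectrogram power
  lhs <- sum(Mod(m$complex_full)^2) / prod(m$source_shape)
  expect_lt(abs(lhs / m$source_power - 1), 1e-9)
  # peak away from DC sits at wt = +/-4 Hz, wf ~ 0
  amp <- m$amplitude
  amp[abs(m$wt) <= 1, ] <- 0
  pk <- which(amp == max(amp), arr.ind = TRUE)[1, ]
  expect_lt(abs(abs(m$wt[pk[1]]) - 4), 0.5)
  expect_lt(m$wf[pk[2]], 0.3)

  # constant spectrogram: all power at the DC cell
  spc <- spa
  spc$values[] <- 3
  mc <- compute_mps(spc)
  off_dc <- mc$amplitude
  off_dc[which(mc$wt == 0), which(mc$wf == 0)] <- 0
  expect_lt(max(off_dc), 1e-8)
})

test_that("modulation filtering attenuates targeted modulations and only those", {
  rate <- 16000
  spa <- compute_spectrogram(am_tone(dur = 2, fm = 4), rate)
  # all-pass: identity to machine precision
  allpass <- modulation_filter("temporal_lowpass", corner = 1e9)
  expect_lt(max(abs(apply_modulation_filter(spa, allpass,
                                            restore_power = FALSE)$values -
                      spa$values)), 1e-8)

  # temporal low-pass at 3 Hz removes the 4 Hz AM line by >= 20 dB
  f3 <- modulation_filter("temporal_lowpass", corner = 3)
  m0 <- compute_mps(spa)
  m1 <- compute_mps(apply_modulation_filter(spa, f3))
  i4 <- which.min(abs(m0$wt - 4))
  att <- 10 * log10(sum(m0$amplitude[i4, ]^2) / sum(m1$amplitude[i4, ]^2))
  expect_gt(att, 20)

  # spectral low-pass at 0.5 cyc/kHz removes 100 Hz harmonic ripple
  # (10 cyc/kHz) by >= 20 dB
  sph <- compute_spectrogram(harmonic_stack(f0 = 100), rate)
  f05 <- modulation_filter("spectral_lowpass", corner = 0.5)
  sphf <- apply_modulation_filter(sph, f05)
  mh0 <- compute_mps(sph); mh1 <- compute_mps(sphf)
  i10 <- which.min(abs(mh0$wf - 10))
  rng <- max(1, i10 - 2):min(length(mh0$wf), i10 + 2)
  att_r <- 10 * log10(sum(mh0$amplitude[, rng]^2) /
                        sum(mh1$amplitude[, rng]^2))
  expect_gt(att_r, 20)

  # DC (0,0) modulation component is never altered
  m1f <- compute_mps(apply_modulation_filter(spa, f3,
                                             restore_power = FALSE))
  dc0 <- mean(spa$values)
  dc1 <- mean(apply_modulation_filter(spa, f3,
                                      restore_power = FALSE)$values)
  expect_lt(abs(dc0 - dc1), 1e-8)

  # per-band time-averaged power is restored after filtering
  A0 <- 10^(spa$values / 20)
  A1 <- 10^(apply_modulation_filter(spa, f3)$values / 20)
  keep <- colMeans(A0^2) > 1e-4 * max(colMeans(A0^2))
  expect_lt(max(abs(colMeans(A1^2)[keep] / colMeans(A0^2)[keep] - 1)), 0.05)
})

test_that("modulation filtering is idempotent", {
  rate <- 16000
  spa <- compute_spectrogram(am_tone(dur = 1.5, fm = 6), rate)
  # brick-wall temporal filter: exact idempotence
  bw <- modulation_filter("temporal_lowpass", corner = 3,
                          transition_width = 0)
  once <- apply_modulation_filter(spa, bw)
  twice <- apply_modulation_filter(once, bw)
  expect_lt(max(abs(twice$values - once$values)), 1e-8)
  # brick-wall spectral filter without power restoration: exact
  bs <- modulation_filter("spectral_lowpass", corner = 0.5,
                          transition_width = 0)
  once_s <- apply_modulation_filter(spa, bs, restore_power = FALSE)
  twice_s <- apply_modulation_filter(once_s, bs, restore_power = FALSE)
  expect_lt(max(abs(twice_s$values - once_s$values)), 1e-8)
  # default raised-cosine filter: near-idempotent (transition band only)
  rc <- modulation_filter("temporal_lowpass", corner = 3)
  once_rc <- apply_modulation_filter(spa, rc)
  twice_rc <- apply_modulation_filter(once_rc, rc)
  rel <- sqrt(sum((twice_rc$values - once_rc$values)^2) /
                sum(once_rc$values^2))
  expect_lt(rel, 0.05)
})

test_that("iterative inversion reconstructs spectrograms and tones", {
  rate <- 16000
  x <- generate_speech_like_sound(1.5, rate, seed = 9)
  sp <- compute_spectrogram(x, rate)
  y <- invert_spectrogram(sp, n_iter = 30, seed = 1)
  sp2 <- compute_spectrogram(y, rate)
  expect_gte(cor(as.numeric(sp$values), as.numeric(sp2$values)), 0.95)

  # relative magnitude error is non-increasing in the iteration budget
  e1 <- attr(invert_spectrogram(sp, n_iter = 1, seed = 1),
             "magnitude_error")
  e10 <- attr(invert_spectrogram(sp, n_iter = 10, seed = 1),
              "magnitude_error")
  e30 <- attr(y, "magnitude_error")
  expect_lte(e10, e1)
  expect_lte(e30, e10)

  # a pure-tone spectrogram inverts to a tone at the same frequency
  t <- (0:(1.2 * rate - 1)) / rate
  spt <- compute_spectrogram(sin(2 * pi * 500 * t), rate)
  yt <- invert_spectrogram(spt, n_iter = 20, seed = 2)
  spec <- Mod(fft(yt))[1:(length(yt) %/% 2)]
  fpk <- (which.max(spec) - 1) * rate / length(yt)
  expect_lt(abs(fpk - 500), rate / spt$nfft + 1)
})

test_that("filtered-speech synthesis preserves RMS and removes fast envelopes", {
  rate <- 16000
  t <- (0:(2 * rate - 1)) / rate
  # 7 Hz syllabic envelope on a 1 kHz carrier
  x <- (1 + cos(2 * pi * 7 * t)) / 2 * sin(2 * pi * 1000 * t)
  f3 <- modulation_filter("temporal_lowpass", corner = 3)
  y <- synthesize_filtered_speech(x, rate, f3, n_iter = 15, seed = 1)
  expect_equal(length(y), length(x))
  expect_lt(abs(rms(y) / rms(x) - 1), 0.01)
  env_spec <- function(z) {
    env <- Mod(strfshift:::analytic_signal(z))
    env <- env - mean(env)
    Mod(fft(env))[1:(length(env) %/% 2)]
  }
  f_axis <- (0:(length(x) %/% 2 - 1)) / 2
  hi <- f_axis > 5 & f_axis < 20
  drop_db <- 20 * log10(max(env_spec(x)[hi]) / max(env_spec(y)[hi]))
  expect_gt(drop_db, 15)
})
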