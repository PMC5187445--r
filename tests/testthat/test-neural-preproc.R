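test_that("raw preprocessing notches line noise and re-references", {
  rate <- 1000
  t <- (0:(4 * rate - 1)) / rate
  line <- sin(2 * pi * 60 * t)
  raw <- rbind(line + rnorm(length(t), sd = 0.05),
               0.8 * line + rnorm(length(t), sd = 0.05),
               rnorm(length(t), sd = 0.05))
  out <- preprocess_raw(raw, rate)
  # 60 Hz content reduced by >= 30 dB
  p60 <- function(x) {
    X <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * rate
    sum(X[f > 58 & f < 62])
  }
  expect_gt(10 * log10(p60(raw[1, ]) / p60(out$values[1, ])), 30)

  # identical signals on all electrodes vanish after common-average
  same <- matrix(rep(sin(2 * pi * 7 * t), 3), 3, byrow = TRUE)
  expect_lt(max(abs(preprocess_raw(same, rate)$values)), 1e-6)

  # zero-phase: a symmetric pulse keeps its peak sample
  pulse <- exp(-((t - 2) / 0.05)^2)
  outp <- preprocess_raw(rbind(pulse, -pulse), rate)
  expect_equal(which.max(outp$values[1, ]), which.max(pulse))

  # high-variance channels are flagged and excluded from the average
  noisy <- rbind(raw, rnorm(length(t), sd = 30))
  expect_true(4 %in% preprocess_raw(noisy, rate)$bad_channels)
  expect_error(preprocess_raw(raw, 200), ">= 500")
})

test_that("HFB extraction follows band-limited amplitude", {
  rate <- 1000
  t <- (0:(6 * rate - 1)) / rate
  # in-band tone: flat trace, monotone in amplitude
  resp <- vapply(c(0.5, 1, 2), function(a) {
    h <- extract_hfb(matrix(a * sin(2 * pi * 100 * t), 1), rate)
    mean(h$values[1, ])
  }, numeric(1))
  # per-band z-normalization makes level differences vanish in the output,
  # but the pre-normalization envelope is amplitude-equivariant
  env_of <- function(a) {
    xb <- signal::filtfilt(signal::butter(2, c(95, 105) / (rate / 2),
                                          "pass"), a * sin(2 * pi * 100 * t))
    mean(Mod(strfshift:::analytic_signal(as.numeric(xb))))
  }
  expect_equal(env_of(2) / env_of(1), 2, tolerance = 1e-6)

  # broadband burst in 70-140 Hz: elevated during, near baseline outside
  set.seed(1)
  carrier <- rnorm(length(t))
  bp <- signal::butter(4, c(70, 140) / (rate / 2), "pass")
  burst_sig <- as.numeric(signal::filtfilt(bp, carrier))
  gate <- as.numeric(t >= 3 & t < 3.5)
  x <- burst_sig * gate + rnorm(length(t), sd = 0.01)
  h <- extract_hfb(matrix(x, 1), rate)
  ht <- (seq_len(ncol(h$values)) - 1) / h$rate
  inside <- mean(h$values[1, ht > 3.05 & ht < 3.45])
  outside <- mean(h$values[1, ht < 2.8 | ht > 3.7])
  expect_gt(inside, outside + 1)

  # out-of-band 10 Hz tone: its pre-normalization band envelope is < 5% of
  # an equal-amplitude in-band tone's
  env_at_100 <- function(x) {
    xb <- signal::filtfilt(signal::butter(2, c(87.5, 112.5) / (rate / 2),
                                          "pass"), x)
    mean(Mod(strfshift:::analytic_signal(as.numeric(xb))))
  }
  expect_lt(env_at_100(sin(2 * pi * 10 * t)) /
              env_at_100(sin(2 * pi * 100 * t)), 0.05)
})

test_that("epoching z-scores against each trial's own baseline", {
  set.seed(2)
  rate <- 50
  hfb <- matrix(rnorm(2 * 3000), 2)
  onsets <- c(500, 1500, 2500)
  ep <- epoch_and_baseline(hfb, rate, onsets, window = c(-1, 2),
                           baseline = c(-0.8, -0.1))
  bidx <- ep$times >= -0.8 & ep$times <= -0.1
  for (k in 1:3) for (e in 1:2) {
    expect_lt(abs(mean(ep$epochs[k, bidx, e])), 1e-12)
    expect_equal(sd(ep$epochs[k, bidx, e]), 1, tolerance = 1e-12)
  }
  # shifting all onsets shifts the epochs
  ep2 <- epoch_and_baseline(hfb, rate, onsets + 7, window = c(-1, 2))
  expect_equal(ep2$epochs[1, 1, 1],
               (hfb[1, 500 + 7 - 50] - mean(hfb[1, (500 + 7 - 40):(500 + 7 - 5)])) /
                 sd(hfb[1, (500 + 7 - 40):(500 + 7 - 5)]), tolerance = 1e-10)
  # a +2 s.d. evoked step is recovered as a post-stimulus z near 2
  base <- matrix(rnorm(1 * 5000), 1)
  on <- seq(600, 4400, by = 400)
  for (o in on) base[1, o:(o + 100)] <- base[1, o:(o + 100)] + 2
  eps <- epoch_and_baseline(base, rate, on, window = c(-1, 2))
  post <- eps$times > 0 & eps$times < 2
  expect_lt(abs(mean(eps$epochs[, post, 1]) - 2), 0.3)
})

test_that("Speech-R selection accepts strong responders and rejects nulls", {
  set.seed(3)
  n_tr <- 20; n_t <- 100
  times <- seq(-1, by = 0.02, length.out = n_t)
  strong <- array(0, c(n_tr, n_t, 2))
  strong[, times > 0, 1] <- 3 + rnorm(sum(times > 0) * n_tr, sd = 0.1)
  strong[, , 2] <- rnorm(n_tr * n_t)  # null electrode
  sel <- select_speech_responsive(strong, times = times, n_boot = 2000)
  expect_true(sel$selected[1])
  # constant-zero electrode: degenerate CI at 0 is not selected
  zero <- array(0, c(12, n_t, 1))
  expect_false(select_speech_responsive(zero, times = times,
                                        n_boot = 500)$selected[1])
  # null false-positive rate is near the nominal 0.5%
  nulls <- array(rnorm(n_tr * n_t * 150), c(n_tr, n_t, 150))
  seln <- select_speech_responsive(nulls, times = times, n_boot = 1000,
                                   seed = 4)
  expect_lte(mean(seln$selected), 0.03)
})
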