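# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# sinusoid with sinusoidal amplitude modulation
am_tone <- function(dur = 2, rate = 16000, fc = 1000, fm = 4, depth = 1) {
  t <- (0:(dur * rate - 1)) / rate
  (1 + depth * cos(2 * pi * fm * t)) / 2 * sin(2 * pi * fc * t)
}

# harmonic stack with given fundamental (constant over time)
harmonic_stack <- function(dur = 1.5, rate = 16000, f0 = 100, n_harm = 40) {
  t <- (0:(dur * rate - 1)) / rate
  rowSums(sapply(seq_len(n_harm), function(k)
    sin(2 * pi * k * f0 * t) / sqrt(k)))
}

# smooth random low-pass stimulus matrix (time x band), cheap stand-in for
# an auditory spectrogram in model-level tests
smooth_stimulus <- function(n_time, n_band = 32, seed = 1, cutoff = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n_time * n_band), n_time, n_band)
  k <- 7
  kern <- exp(-0.5 * ((-k:k) / 2.5)^2); kern <- kern / sum(kern)
  X <- apply(X, 2, function(col) stats::filter(col, kern, circular = TRUE))
  abs(X)
}

# small Gabor STRF with fixed parameters
test_gabor <- function(seed = 3) {
  strfshift:::with_seed(seed, strfshift:::random_gabor_strf())
}

# small speech-like stimulus spectrograms at 50 Hz (expensive; memoized)
speech_specs <- function(n = 4, dur = 2, seed0 = 500) {
  fixture(sprintf("specs_%d_%g_%d", n, dur, seed0), {
    lapply(seq_len(n), function(k) {
      s <- generate_speech_like_sound(dur, 16000, seed = seed0 + k)
      auditory_spectrogram(s, 16000)$values
    })
  })
}

# one small synthetic experiment shared across test files (expensive)
tiny_cfg <- function() synthetic_config(n_trials = 4, n_electrodes = 6,
                                        trial_duration = 2, seed = 11)
tiny_stim <- function() fixture("tiny_stim",
                                generate_stimulus_set(tiny_cfg()))
tiny_experiment <- function() fixture(
  "tiny_experiment", generate_experiment(tiny_cfg(), stimuli = tiny_stim()))
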