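# Audio and array-container I/O.
#
# WAV support is a minimal single-channel 16-bit PCM RIFF reader/writer --
# enough for stimulus files -- since the analysis itself only needs mono
# waveforms in [-1, 1].

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param x Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, rate, path) {
  check_scalar(rate, "rate", lower = 1)
  x <- pmax(-1, pmin(1, as.numeric(x)))
  samples <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(samples) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path Path to a WAV file as written by [write_wav()] (PCM, mono,
#'   16-bit).
#' @return List with `wave` (numeric in `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF/WAV file: %s", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  readChar(con, 4)  # "WAVE"
  rate <- NULL; bits <- NULL; channels <- NULL; wave <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (identical(tag, "data")) {
      wave <- readBin(con, "integer", n = size / 2, size = 2,
                      signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  if (is.null(wave) || is.null(rate))
    stop_invalid("malformed WAV file: %s", path)
  if (!identical(channels, 1L) || !identical(bits, 16L))
    stop_invalid("only mono 16-bit PCM WAV is supported")
  list(wave = wave / 32767, rate = rate)
}

# Trial-set array container ---------------------------------------------------
#
# A trial set is stored as a plain-text/WAV directory (documented layout):
#   meta.yaml                      experiment parameters, axes, seeds
#   audio/trial<K>_filtered.wav    stimulus audio (BEFORE and AFTER share the
#   audio/trial<K>_unfiltered.wav  filtered file by task design)
#   hfb_<cond>.tsv                 rows = electrodes, columns = trial-major
#                                  (trial, time) HFB samples
#   truth/strf_<cond>.tsv          rows = electrodes, columns = lag-major
#                                  (lag, band) ground-truth gains

write_matrix_tsv <- function(M, path) {
  utils::write.table(format(M, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t",
                              colClasses = "numeric"))
}

#' Save a synthetic trial set to a plain-text directory container
#'
#' @param trialset A `trialset` from [generate_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_trialset <- function(trialset, dir) {
  stopifnot(inherits(trialset, "trialset"))
  dir.create(file.path(dir, "audio"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (k in seq_len(trialset$n_trials)) {
    write_wav(trialset$audio[[k]]$filtered, trialset$audio_rate,
              file.path(dir, "audio", sprintf("trial%02d_filtered.wav", k)))
    write_wav(trialset$audio[[k]]$unfiltered, trialset$audio_rate,
              file.path(dir, "audio",
                        sprintf("trial%02d_unfiltered.wav", k)))
  }
  for (cond in c("before", "middle", "after")) {
    h <- trialset$hfb[[cond]]                     # el x time x trial
    flat <- matrix(aperm(h, c(1, 2, 3)), nrow = dim(h)[1])
    write_matrix_tsv(flat, file.path(dir, sprintf("hfb_%s.tsv", cond)))
    G <- trialset$truth[[paste0("strf_", cond)]]  # lag x band x el
    gm <- t(vapply(seq_len(dim(G)[3]), function(e) strf_vec(G[, , e]),
                   numeric(dim(G)[1] * dim(G)[2])))
    write_matrix_tsv(gm, file.path(dir, "truth",
                                   sprintf("strf_%s.tsv", cond)))
  }
  meta <- list(n_trials = trialset$n_trials,
               n_electrodes = trialset$n_electrodes,
               audio_rate = trialset$audio_rate,
               hfb_rate = trialset$hfb_rate,
               n_time = dim(trialset$hfb$before)[2],
               times_start = trialset$times[1],
               lags_s = as.numeric(trialset$lags_s),
               band_centers = as.numeric(trialset$band_centers),
               shift_lambda = trialset$truth$shift_lambda,
               snr = if (is.finite(trialset$truth$snr))
                 trialset$truth$snr else "Inf",
               seed = trialset$truth$seed)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load a trial set written by [save_trialset()]
#'
#' Audio, HFB responses and ground truths are restored; reduced auditory
#' spectrograms are not stored and can be recomputed from the audio with
#' [auditory_spectrogram()].
#'
#' @param dir Container directory.
#' @return A `trialset` (with `spec = NULL`).
#' @export
load_trialset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  n_lag <- length(meta$lags_s); n_band <- length(meta$band_centers)
  audio <- lapply(seq_len(meta$n_trials), function(k) list(
    filtered = read_wav(file.path(
      dir, "audio", sprintf("trial%02d_filtered.wav", k)))$wave,
    unfiltered = read_wav(file.path(
      dir, "audio", sprintf("trial%02d_unfiltered.wav", k)))$wave))
  hfb <- list(); truth <- list(shift_lambda = meta$shift_lambda,
                               snr = as.numeric(meta$snr),
                               seed = meta$seed, lags_s = meta$lags_s)
  for (cond in c("before", "middle", "after")) {
    flat <- read_matrix_tsv(file.path(dir, sprintf("hfb_%s.tsv", cond)))
    hfb[[cond]] <- array(flat, c(meta$n_electrodes, meta$n_time,
                                 meta$n_trials))
    gm <- read_matrix_tsv(file.path(dir, "truth",
                                    sprintf("strf_%s.tsv", cond)))
    truth[[paste0("strf_", cond)]] <- array(
      apply(gm, 1, strf_unvec, n_lag = n_lag, n_band = n_band),
      c(n_lag, n_band, meta$n_electrodes))
  }
  class(truth) <- "synthetic_truth"
  structure(list(audio = audio, spec = NULL, hfb = hfb, truth = truth,
                 times = meta$times_start +
                   (seq_len(meta$n_time) - 1) / meta$hfb_rate,
                 band_centers = meta$band_centers,
                 lags_s = meta$lags_s,
                 n_trials = meta$n_trials,
                 n_electrodes = meta$n_electrodes,
                 audio_rate = meta$audio_rate,
                 hfb_rate = meta$hfb_rate,
                 config = NULL), class = "trialset")
}
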