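# End-to-end orchestration of the plasticity analysis.
#
# Stage order mirrors the experiment's analysis: data (synthetic or loaded)
# -> baselined epochs -> Speech-R selection -> condition-wise eSTRF fits at a
# single global ridge penalty -> STRF-R selection -> electrode intersection
# -> coherence/MI similarity contrast -> MTF / output-power / generalization
# / partial-correlation contrasts -> sign-flip and cluster permutation
# statistics -> report files.

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (default) or `"from_files"`.
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param trialset_dir Directory of a saved trial set (from-files mode).
#' @param out_dir Output directory for report files (`NULL` = no files).
#' @param n_perm Permutations for the sign-flip and cluster tests.
#' @param n_boot Bootstrap resamples for Speech-R selection.
#' @param electrode_whitelist Integer indices of anatomically eligible
#'   electrodes (`NULL` = all; the synthetic brain has no anatomy).
#' @param stages Named logical toggles: `coherence`, `mtf`, `contrasts`,
#'   `evoked`.
#' @param seed Seed for all resampling statistics.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "from_files"),
                       synthetic = synthetic_config(),
                       trialset_dir = NULL, out_dir = NULL,
                       n_perm = 10000, n_boot = 10000,
                       electrode_whitelist = NULL,
                       stages = list(), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "from_files" &&
      (is.null(trialset_dir) || !dir.exists(trialset_dir)))
    stop_invalid("from_files mode needs an existing trialset_dir")
  st <- utils::modifyList(list(coherence = TRUE, mtf = TRUE,
                               contrasts = TRUE, evoked = TRUE), stages)
  structure(list(mode = mode, synthetic = synthetic,
                 trialset_dir = trialset_dir, out_dir = out_dir,
                 n_perm = n_perm, n_boot = n_boot,
                 electrode_whitelist = electrode_whitelist,
                 stages = st, seed = seed), class = "run_config")
}

baseline_zscore_epochs <- function(hfb_cond, times, baseline = c(-0.8, -0.1)) {
  # hfb_cond: electrode x time x trial -> trial x time x electrode, z-scored
  # per trial/electrode against the baseline window
  ep <- aperm(hfb_cond, c(3, 2, 1))
  bidx <- which(times >= baseline[1] & times <= baseline[2])
  if (length(bidx) < 2) stop_invalid("no baseline samples in epoch window")
  for (e in seq_len(dim(ep)[3])) {
    b <- ep[, bidx, e, drop = FALSE]
    bmean <- rowMeans(b, dims = 1)
    bsd <- apply(b[, , 1, drop = TRUE], 1, stats::sd)
    ep[, , e] <- (ep[, , e] - bmean) / pmax(bsd, .Machine$double.eps)
  }
  ep
}

#' Run the full analysis pipeline
#'
#' @param config A [run_config()].
#' @param stimuli Optional precomputed [generate_stimulus_set()] output
#'   (synthetic mode only), reused to avoid regenerating audio.
#' @return A `pipeline_result` list; see Details.
#' @details The result contains `trialset`, `selection` (Speech-R, STRF-R,
#'   intersection), `fits` (per condition, at the shared global ridge),
#'   `global_ridge`, `coherence` (per-electrode MI contrast table and its
#'   sign-flip test), `contrasts` (per-electrode `delta_rho`, `delta_rms`,
#'   `delta_r2` and group tests), `evoked` (AFTER-BEFORE cluster test),
#'   `mtf` (difference maps and group test), and a `summary` data frame.
#'   All stages are deterministic given the configuration.
#' @export
run_pipeline <- function(config, stimuli = NULL) {
  stopifnot(inherits(config, "run_config"))
  res <- list(config = config)

  # --- data ------------------------------------------------------------
  ts <- if (config$mode == "synthetic") {
    generate_experiment(config$synthetic, stimuli = stimuli)
  } else {
    load_trialset(config$trialset_dir)
  }
  if (is.null(ts$spec)) {
    # recompute reduced auditory spectrograms from stored audio
    pad_pre <- -ts$times[1]
    n_time <- length(ts$times)
    pad <- function(x, total) {
      n_pre <- round(pad_pre * ts$audio_rate)
      out <- c(numeric(n_pre), x)
      c(out, numeric(max(0, total - length(out))))
    }
    total <- round((ts$times[n_time] + 1 / ts$hfb_rate + pad_pre) *
                     ts$audio_rate)
    mk <- function(field) {
      arr <- NULL
      for (k in seq_len(ts$n_trials)) {
        S <- auditory_spectrogram(pad(ts$audio[[k]][[field]], total),
                                  ts$audio_rate, rate = ts$hfb_rate)
        v <- S$values[seq_len(n_time), , drop = FALSE]
        if (is.null(arr)) arr <- array(NA_real_, c(dim(v), ts$n_trials))
        arr[, , k] <- v
      }
      arr
    }
    Sf <- mk("filtered"); Su <- mk("unfiltered")
    ts$spec <- list(before = Sf, middle = Su, after = Sf)
  }
  res$trialset <- ts
  times <- ts$times
  conds <- c("before", "middle", "after")

  # --- epochs + Speech-R ----------------------------------------------
  epochs <- lapply(ts$hfb, baseline_zscore_epochs, times = times)
  speech_r <- select_speech_responsive(epochs$middle, times = times,
                                       n_boot = config$n_boot,
                                       seed = config$seed)
  res$speech_r <- speech_r

  # --- condition-wise eSTRF fits at a single global ridge --------------
  n_lags <- length(strf_lags(ts$hfb_rate))
  trial_S <- function(cond) lapply(seq_len(ts$n_trials),
                                   function(k) ts$spec[[cond]][, , k])
  trial_R <- function(cond) lapply(seq_len(ts$n_trials),
                                   function(k) t(ts$hfb[[cond]][, , k]))
  fits0 <- lapply(conds, function(cond)
    fit_condition_strfs(trial_S(cond), trial_R(cond), n_lags = n_lags,
                        keep_solvers = TRUE))
  names(fits0) <- conds
  active <- which(speech_r$selected)
  if (!length(active)) active <- seq_len(ts$n_electrodes)
  argmaxes <- unlist(lapply(fits0, function(fl)
    lapply(fl[active], `[[`, "fold_argmax")))
  global_ridge <- select_global_ridge(argmaxes, strf_ridge_grid())
  fits <- lapply(fits0, refit_condition_strfs, ridge = global_ridge)
  res$global_ridge <- global_ridge
  res$fits <- fits

  # --- STRF-R + intersection ------------------------------------------
  strf_r <- vapply(fits$middle, select_strf_responsive, logical(1))
  whitelist <- rep(FALSE, ts$n_electrodes)
  wl <- config$electrode_whitelist
  if (is.null(wl)) wl <- seq_len(ts$n_electrodes)
  whitelist[wl] <- TRUE
  selected <- speech_r$selected & strf_r & whitelist
  res$selection <- list(speech_r = speech_r$selected, strf_r = strf_r,
                        whitelist = whitelist, selected = selected,
                        n_speech_r = sum(speech_r$selected),
                        n_strf_r = sum(strf_r), n_selected = sum(selected))
  sel_idx <- which(selected)
  if (!length(sel_idx)) {
    warning("no electrode passed Speech-R & STRF-R; using all electrodes")
    sel_idx <- seq_len(ts$n_electrodes)
  }

  # --- coherence / MI contrast ----------------------------------------
  if (isTRUE(config$stages$coherence)) {
    coh_tab <- condition_similarity_contrast(epochs, ts$hfb_rate, times)
    coh_raw_tab <- condition_similarity_contrast(epochs, ts$hfb_rate,
                                                 times,
                                                 subtract_global = FALSE)
    coh_test <- signflip_permutation_test(
      coh_tab$delta_bits[sel_idx], n_perm = config$n_perm,
      seed = derive_seed(config$seed, "coh"))
    res$coherence <- list(table = coh_tab, table_unsubtracted = coh_raw_tab,
                          test = coh_test)
  }

  # --- tuning contrasts ------------------------------------------------
  if (isTRUE(config$stages$contrasts)) {
    shift_tab <- tuning_shift_contrast(fits)
    S_mid <- trial_S("middle")
    out_pow <- t(vapply(seq_len(ts$n_electrodes), function(e) {
      c(before = speech_output_power(fits$before[[e]], S_mid,
                                     standardize_stimuli = TRUE),
        after = speech_output_power(fits$after[[e]], S_mid,
                                    standardize_stimuli = TRUE))
    }, numeric(2)))
    gen <- t(vapply(seq_len(ts$n_electrodes), function(e) {
      rb <- lapply(seq_len(ts$n_trials), function(k) ts$hfb$before[e, , k])
      ra <- lapply(seq_len(ts$n_trials), function(k) ts$hfb$after[e, , k])
      c(before = as.numeric(generalization_score(fits$middle[[e]],
                                                 trial_S("before"), rb)),
        after = as.numeric(generalization_score(fits$middle[[e]],
                                                trial_S("after"), ra)))
    }, numeric(2)))
    tab <- data.frame(
      electrode = seq_len(ts$n_electrodes),
      selected = selected,
      delta_rho = shift_tab$delta_rho,
      rms_before = out_pow[, "before"], rms_after = out_pow[, "after"],
      delta_rms = out_pow[, "after"] - out_pow[, "before"],
      r2_gen_before = gen[, "before"], r2_gen_after = gen[, "after"],
      delta_r2 = gen[, "after"] - gen[, "before"])
    tests <- list(
      delta_rho = signflip_permutation_test(
        tab$delta_rho[sel_idx], n_perm = config$n_perm,
        seed = derive_seed(config$seed, "rho")),
      delta_rms = signflip_permutation_test(
        tab$delta_rms[sel_idx], n_perm = config$n_perm,
        seed = derive_seed(config$seed, "rms")),
      delta_r2 = signflip_permutation_test(
        tab$delta_r2[sel_idx], n_perm = config$n_perm,
        seed = derive_seed(config$seed, "r2")))
    res$contrasts <- list(table = tab, tests = tests)
  }

  # --- evoked HFB AFTER-BEFORE cluster test ---------------------------
  if (isTRUE(config$stages$evoked)) {
    D <- t(vapply(sel_idx, function(e)
      colMeans(epochs$after[, , e] - epochs$before[, , e]),
      numeric(length(times))))
    res$evoked <- cluster_permutation_test(
      D, n_perm = min(config$n_perm, 2000),
      seed = derive_seed(config$seed, "evoked"))
  }

  # --- MTF contrast ----------------------------------------------------
  if (isTRUE(config$stages$mtf)) {
    mtf <- mtf_condition_contrast(fits, lags_s = strf_lags(ts$hfb_rate),
                                  band_centers = ts$band_centers)
    corner_wt <- if (!is.null(ts$config) &&
                     ts$config$filter_type == "temporal_lowpass") 3 else
                       max(abs(mtf$wt)) / 4
    region <- abs(mtf$wt) <= corner_wt
    region_mean <- apply(mtf$maps[, region, , drop = FALSE], 1, mean)
    res$mtf <- list(maps = mtf, region_mean = region_mean,
                    test = signflip_permutation_test(
                      region_mean[sel_idx], n_perm = config$n_perm,
                      seed = derive_seed(config$seed, "mtf")))
  }

  # --- summary ---------------------------------------------------------
  res$summary <- pipeline_summary(res)
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

pipeline_summary <- function(res) {
  rows <- list(
    data.frame(quantity = "n_electrodes",
               value = res$trialset$n_electrodes, p = NA_real_),
    data.frame(quantity = "n_speech_r", value = res$selection$n_speech_r,
               p = NA_real_),
    data.frame(quantity = "n_strf_r", value = res$selection$n_strf_r,
               p = NA_real_),
    data.frame(quantity = "n_selected", value = res$selection$n_selected,
               p = NA_real_),
    data.frame(quantity = "global_ridge", value = res$global_ridge,
               p = NA_real_))
  sel <- which(res$selection$selected)
  if (!length(sel)) sel <- seq_len(res$trialset$n_electrodes)
  if (!is.null(res$coherence)) {
    rows <- c(rows, list(data.frame(
      quantity = "delta_mi_bits",
      value = res$coherence$test$observed,
      p = res$coherence$test$p_two_sided)))
  }
  if (!is.null(res$contrasts)) {
    for (nm in names(res$contrasts$tests)) {
      tst <- res$contrasts$tests[[nm]]
      rows <- c(rows, list(data.frame(quantity = nm, value = tst$observed,
                                      p = tst$p_two_sided)))
    }
  }
  if (!is.null(res$evoked)) {
    p <- if (nrow(res$evoked$clusters)) min(res$evoked$clusters$p) else
      NA_real_
    rows <- c(rows, list(data.frame(
      quantity = "evoked_min_cluster_p",
      value = if (nrow(res$evoked$clusters))
        res$evoked$clusters$mass[which.min(res$evoked$clusters$p)] else 0,
      p = p)))
  }
  if (!is.null(res$mtf)) {
    rows <- c(rows, list(data.frame(quantity = "mtf_region_shift",
                                    value = res$mtf$test$observed,
                                    p = res$mtf$test$p_two_sided)))
  }
  do.call(rbind, rows)
}

#' Write pipeline report files
#'
#' Writes `summary.tsv` (headline quantities and p-values),
#' `electrodes.tsv` (per-electrode selection flags and contrast values),
#' `coherence.tsv` (per-electrode MI by window group), and
#' `provenance.yaml` (configuration, seeds, package version) to `dir`.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(res, dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  eltab <- data.frame(electrode = seq_len(res$trialset$n_electrodes),
                      speech_r = res$selection$speech_r,
                      strf_r = res$selection$strf_r,
                      selected = res$selection$selected)
  if (!is.null(res$contrasts))
    eltab <- cbind(eltab, res$contrasts$table[
      setdiff(names(res$contrasts$table), c("electrode", "selected"))])
  utils::write.table(eltab, file.path(dir, "electrodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$coherence))
    utils::write.table(res$coherence$table,
                       file.path(dir, "coherence.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  prov <- list(
    package_version = as.character(utils::packageVersion("strfshift")),
    r_version = R.version.string,
    mode = res$config$mode,
    seed = res$config$seed,
    n_perm = res$config$n_perm,
    n_boot = res$config$n_boot,
    global_ridge = res$global_ridge,
    synthetic = if (res$config$mode == "synthetic")
      unclass(res$config$synthetic) else NULL)
  if (!is.null(prov$synthetic) && !is.finite(prov$synthetic$snr))
    prov$synthetic$snr <- "Inf"
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back a written pipeline report
#'
#' @param dir Report directory written by [write_report()].
#' @return List with `summary`, `electrodes`, `coherence` (if present) and
#'   `provenance`.
#' @export
read_report <- function(dir) {
  out <- list(
    summary = utils::read.table(file.path(dir, "summary.tsv"),
                                header = TRUE, sep = "\t"),
    electrodes = utils::read.table(file.path(dir, "electrodes.tsv"),
                                   header = TRUE, sep = "\t"),
    provenance = yaml::read_yaml(file.path(dir, "provenance.yaml")))
  coh <- file.path(dir, "coherence.tsv")
  if (file.exists(coh))
    out$coherence <- utils::read.table(coh, header = TRUE, sep = "\t")
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
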