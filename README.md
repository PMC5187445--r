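# strfshift

Analysis pipeline for detecting **rapid shifts in spectrotemporal tuning of
human auditory cortex** during a filtered-speech listening task, with a
synthetic-experiment generator that makes every stage testable without
clinical recordings.

## The problem

In the paradigm this package analyses, a listener hears a modulation-filtered
(degraded) sentence (**BEFORE**), then the intact sentence (**MIDDLE**), then
the identical degraded sentence again (**AFTER**). Perceptually, the second
degraded presentation "pops out" as intelligible. The scientific question is
whether this coincides with a change in the stimulus tuning of auditory
cortical populations, measured from electrocorticographic high-frequency
broadband amplitude (HFB, ~70–150 Hz).

Tuning is characterized by an ensemble spectrotemporal receptive field
(eSTRF): a linear filter $g(\tau, p, n)$ predicting electrode $n$'s HFB from
a 32-band auditory spectrogram $S(t, p)$ over causal lags
$\tau \in [0, 400]$ ms,

$$\hat r(t,n) = \sum_\tau \sum_p g(\tau, p, n)\, S(t-\tau, p),$$

estimated by ridge regression with leave-one-trial-out jackknife
cross-validation (single global penalty = mode of per-fold argmax penalties).
Plasticity is quantified by four condition contrasts, each tested with a
sign-flip permutation test across electrodes:

- **MI contrast** — trial-to-trial multitaper coherence between condition
  responses, converted to bits/s via $-\int\log_2(1-\gamma^2(f))\,df$;
  contrast = MI(AFTER, MIDDLE) − MI(BEFORE, MIDDLE).
- **Partial-correlation contrast** —
  $\Delta\rho = \rho(A, M\,|\,B) - \rho(B, M\,|\,A)$ on coefficient t-maps.
- **Output-power contrast** — RMS response of the z-scored BEFORE vs AFTER
  eSTRFs driven by unfiltered-speech spectrograms.
- **Generalization contrast** — $R^2$ of MIDDLE-condition coefficients
  predicting BEFORE vs AFTER responses.

The package also implements the stimulus-creation arm (modulation power
spectrum computation, modulation low-pass filtering at 0.5 cycles/kHz or
3 Hz, iterative spectrogram inversion), the gammatone/ERB auditory front
end, HFB extraction and electrode screening (Speech-R / STRF-R), and
cluster-based and bootstrap resampling inference.

Intended users: auditory/systems neuroscientists working with encoding
models of intracranial recordings, and anyone needing a tested reference
implementation of modulation filtering, jackknifed ridge STRFs, or
coherence-based response similarity.

## Worked example

Simulate a small experiment with a known tuning shift (shift coefficient
λ = 0.8, HFB SNR 4) and run the full pipeline:

```r
library(strfshift)

cfg <- synthetic_config(n_trials = 6, n_electrodes = 12,
                        trial_duration = 2, snr = 4,
                        shift_lambda = 0.8, seed = 1)
res <- run_pipeline(run_config(synthetic = cfg, n_perm = 2000,
                               n_boot = 2000, seed = 1))
print(res$summary, row.names = FALSE)
#>              quantity       value          p
#>          n_electrodes  12.0000000         NA
#>            n_speech_r   6.0000000         NA
#>              n_strf_r  12.0000000         NA
#>            n_selected   6.0000000         NA
#>          global_ridge 316.2277660         NA
#>         delta_mi_bits   2.1595443 0.02898551
#>             delta_rho   0.6693923 0.03448276
#>             delta_rms  43.7415084 0.03398301
#>              delta_r2   1.5308598 0.03748126
#>  evoked_min_cluster_p -41.8891708 0.06646677
#>      mtf_region_shift  -0.2326125 0.25237381
```

Reading the output: 12 simulated electrodes, of which 6 pass the evoked-HFB
(Speech-R) gate and all 12 are well modelled (STRF-R); models share ridge
penalty 316. All four headline contrasts are positive — responses to the
repeated degraded sentence became more MIDDLE-like by ~2.2 bits/s of
coherent information, the AFTER eSTRFs correlate more with the MIDDLE eSTRF
(Δρ = 0.67), respond more strongly to unfiltered speech, and are better
predicted by MIDDLE coefficients — each significant at p < 0.05 even in this
deliberately small example (6 selected electrodes; the study-scale runs in
`scripts/acceptance.R` use 30 electrodes and reach p < 0.001).

Individual stages are ordinary functions: `generate_speech_like_sound()`,
`synthesize_filtered_speech()`, `auditory_spectrogram()`,
`fit_strf_jackknife()`, `multitaper_coherence()`,
`tuning_shift_contrast()`, `signflip_permutation_test()`, and so on; see
the help pages and the methods vignette (`vignettes/strfshift-methods.Rmd`).
A thin command-line front end lives at `inst/exec/strfshift`
(`simulate`, `filter-audio`, `run-all`, `report`).

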