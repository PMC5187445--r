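---
title: "Measuring rapid spectrotemporal tuning shifts: models and methods"
author: "strfshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rapid spectrotemporal tuning shifts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When a listener hears a degraded (modulation-filtered) sentence, then the
intact sentence, then the same degraded sentence again, the second degraded
presentation is suddenly intelligible. `strfshift` implements the analysis
pipeline for asking whether this perceptual "pop-out" coincides with a shift
in the spectrotemporal tuning of auditory cortical populations, as measured
by ensemble spectrotemporal receptive fields (eSTRFs) fit to intracranial
high-frequency broadband (HFB, ~70-150 Hz) amplitude.

The encoding model is linear:

$$\hat r(t, n) = \sum_{\tau} \sum_{p} g(\tau, p, n)\, S(t - \tau, p),$$

with $S(t, p)$ a 32-band auditory spectrogram at 50 Hz, causal lags $\tau$
from 0 to 400 ms (21 lags), and $g$ the eSTRF of electrode $n$. The central
claim under test: after hearing unfiltered speech, the filtered-condition
eSTRF moves toward the unfiltered-condition eSTRF.

## Pipeline stages and their parameters

**Stimulus arm.** Degraded speech is made by low-pass filtering the 2D
Fourier transform of a Gaussian-window log spectrogram (window $\sigma$ =
7.1 ms, hop 2 ms, 50 dB floor) along one modulation axis — spectral
modulations above 0.5 cycles/kHz or temporal modulations above 3 Hz — and
inverting the filtered spectrogram back to audio by iterative phase
retrieval (30 alternating-projection iterations, seeded random phase
initialization). Filter edges are raised cosines spanning 20% of the corner
(a brick wall rings badly through the inversion); the per-band time-averaged
power profile is restored after filtering so the long-term spectrum is
unchanged. For a *spectral* filter the restoring profile is smoothed below
the corner: restoring fine structure (e.g. harmonic ripple) would undo the
filter for quasi-stationary sounds. A consequence worth knowing: with a
raised-cosine edge the filter is only approximately idempotent (gains in the
transition band square on re-application); the brick-wall limit
(`transition_width = 0`) is exactly idempotent and is what the invariant
tests pin down at machine precision.

**Auditory features.** 128 fourth-order gammatone filters on the ERB scale
(Glasberg–Moore), 180–7000 Hz; half-wave rectification, cube-root
compression (the usual cochlear choice; exponent configurable),
first-difference spectral sharpening across bands (half-wave rectified; a
lateral-inhibition stand-in), a leaky integrator with $\tau$ = 8 ms, then
block-averaging of 4 adjacent bands to 32 and resampling to 50 Hz behind a
25 Hz anti-alias low-pass. Envelope-domain anti-aliasing uses a zero-phase
FFT low-pass rather than an IIR design because normalized cutoffs of order
$10^{-3}$ make `filtfilt` numerically fragile.

**HFB extraction (real-data path).** 21 geometric centre frequencies from
70 to 140 Hz, bandwidth 0.25 x centre, zero-phase Butterworth band-passes,
Hilbert modulus, per-band z-normalization before averaging (without it the
1/f spectrum lets low bands dominate), then 50 Hz (model path) and 100 Hz
(coherence path) variants. The synthetic path bypasses this stage: the
generator produces HFB directly at 50 Hz, and coherence on synthetic
experiments therefore runs at 50 Hz (400 ms windows, 20 samples, 3 tapers) —
the statistics are rate-agnostic.

**eSTRF fitting.** Ridge regression on z-scored inputs and outputs
(standardization statistics from the training folds only), leave-one-trial-out
jackknife. The penalty grid is log-spaced $10^{-2}$ to $10^6$ (17 points);
per fold the held-out $R^2$ is recorded for every penalty, and the global
penalty is the mode of the per-fold argmax distribution over active
electrodes, ties broken toward more shrinkage. All conditions share this
single penalty so every model sees the same prior. Per-fold coefficient
estimates give both the coefficient t-map (mean/s.d. across folds) and the
selection statistic: an electrode is STRF-responsive when the 0.5th
percentile of fold $R^2$ exceeds 0 (the two-sided 99% convention; the
matching speech-responsiveness rule bootstraps trial-mean evoked z-scores,
10,000 resamples, and requires the 0.5th percentile above 0). Because the
design matrix depends only on the stimuli, its eigendecomposition is shared
across electrodes, which is what makes hundreds of electrodes cheap to fit.

**Similarity and tuning contrasts.** Between-condition response similarity
is multitaper coherence (nw = 2, 3 Slepian tapers, 400 ms windows, 200 ms
steps, pooled over trials and tapers) debiased by a leave-one-trial-out
jackknife on atanh $\sqrt{\gamma^2}$, and converted to an information rate
$-\int \log_2(1-\gamma^2(f))\,df$ in bits/s. That conversion formula is
reconstructed from the standard coherence-information literature (it is the
Gaussian-channel form); the integrand is clipped at $1 - 10^{-6}$. Tuning
contrasts are: the MTF (2D transform of the STRF after interpolation to a
uniform log-frequency axis, spectral modulation in cycles/octave); the RMS
output power of the z-scored eSTRF driven by unfiltered-speech spectrograms;
the generalization $R^2$ of MIDDLE-condition coefficients on filtered
trials (prediction and observation both z-scored, so only shape is scored);
and the partial-correlation contrast
$\Delta\rho = \rho(A, M \mid B) - \rho(B, M \mid A)$ on the coefficient
t-maps, residualization with an intercept. Group inference is by sign-flip
permutation (10,000 flips, two-sided, +1 convention) and, for time courses,
a cluster-mass permutation test over time (cluster-forming threshold: the
two-sided t critical value at 0.05).

## The synthetic experiment generator

The generator defines the study conditions for every test: nothing
downstream is tested on data it did not produce.

*Stimuli* are not speech but are speech-shaped: a harmonic stack with a
per-sentence pitch (105–215 Hz) drifting ~±5% plus ~1% glottal jitter
(which blurs high harmonics exactly as natural jitter does), 2–4 formant
peaks that jump to new targets every syllable, a 3–8 Hz syllabic envelope
low-passed at 10 Hz with a voicing floor, per-syllable spectral tilt and
aspiration mix, occasional fricative-band noise, and band-limited plosive
bursts at syllable onsets. These choices were made against one yardstick:
the modulation power spectrum must concentrate where speech concentrates it
(most non-DC power below 10 Hz and 3 cycles/kHz), while still exciting
enough independent spectrotemporal dimensions that receptive-field recovery
is well-posed. Each trial is a unique sentence; the BEFORE and AFTER
presentations use the bit-identical filtered audio, the MIDDLE presentation
the unfiltered audio, and every stimulus is padded with silence (1 s before,
0.6 s after) so each epoch has a pre-stimulus baseline.

*Ground truths.* BEFORE truths are random 2D Gabors on the lag x band grid
(centre lag 50–250 ms, temporal envelope $\sigma$ 80–150 ms, temporal
carrier 1–3.5 Hz, spectral envelope 4–8 bands, random orientation and
phase), standardized. The family is deliberately smooth: speech-like
stimuli have syllabic (<10 Hz) envelopes, so the lag-expanded stimulus
covariance has an effective rank near 40 of 672, and faster/sharper filters
are simply not identifiable from such stimuli at realistic noise — which is
also why published ECoG eSTRFs look smooth and temporally extended. MIDDLE
truths add to the Gabor a shared speech-matched component — the dominant
eigenvector of the lag-expanded covariance of a reference speech-like
spectrogram, an envelope-following filter shape — with per-electrode weight
drawn from U(1.0, 1.8), then standardize. This encodes the premise under
test: tuning measured on unfiltered speech *is* speech-feature-matched,
which is what makes output-power and generalization contrasts directional
rather than null by symmetry. AFTER truths are the elementwise
interpolation $(1-\lambda)\,g_{before} + \lambda\,g_{middle}$; $\lambda$ is
scale-free because both ends are standardized first, and the endpoint
identities hold exactly.

*Responses* are the causal convolution of the condition truth with the
trial's auditory spectrogram plus noise scaled so var(signal)/var(noise)
equals the configured SNR (white by default; an AR(1) option with
coefficient 0.7 reflects the temporal correlation of real HFB noise). The
default snr = 4 is a modelling choice, not a claim about any particular
electrode. One knowing divergence from real data: because the truths are
zero-mean, the sign of an electrode's net evoked amplitude is random, so
roughly half of the simulated electrodes fail the speech-responsiveness
gate, whereas real HFB deflects positively. Seeds are split with a
counter-based scheme (`derive_seed`), so any trial or electrode can be
regenerated in isolation and identical configurations are bit-reproducible.

## What the synthetic study shows — and one thing it cannot

At $\lambda = 0.8$, snr = 4, 30 electrodes, 10 unique 3 s sentences, the
pipeline detects the shift in all four headline group contrasts (MI
difference, partial-correlation difference, output-power difference,
generalization-$R^2$ difference; sign-flip p < 0.01), and at $\lambda = 0$
replicates are clean. Three of the four contrasts rise strictly
monotonically over $\lambda \in \{0, 0.25, 0.5, 0.75, 1\}$. The
partial-correlation contrast does not: it saturates and then dips at high
$\lambda$. The reason is intrinsic to partial correlation. For $\lambda$
near 1 the AFTER filter approaches the MIDDLE filter, so conditioning on
AFTER removes nearly all of MIDDLE and $\rho(B, M \mid A)$ rises from a
negative suppression value back toward zero, while $\rho(A, M \mid B)$ is
already at ceiling; their difference therefore peaks at intermediate
$\lambda$. (At the truth level this is exact: for orthogonal truths and any
$0 < \lambda < 1$, $\rho(A, M \mid B) = 1$ while $\rho(B, M \mid A) < 0$,
and at $\lambda = 1$ the latter is 0.) $\Delta\rho$ is a fine *detector* of
a shift but not a *dose meter* of its size near completion.

Passing these tests shows the machinery is correct and calibrated on data
whose generative law matches the model class. It does not show that real
cortical responses are linear in the auditory spectrogram, that real noise
is white, or that real plasticity is an interpolation between two fixed
filters.

## Numerical choices and degenerate inputs

- Problem sizes in the test-suite study (10 trials x 3 s, 30 electrodes,
  8 recovery electrodes, 2000 permutations/bootstraps where the full
  10,000 would only polish the third decimal) were chosen so the whole
  suite runs comfortably on one CPU.
- Permutation p-values use the +1 convention and never return 0; an
  all-zero difference vector returns p = 1.
- Coherence of identical signals is clipped at $1 - 10^{-12}$ before the
  atanh transform; debiased coherence may legitimately dip below 0 and is
  clipped at 0 only inside the information integral.
- A constant STRF has no z-score and output power raises an error; an
  input fully explained by the conditioning variable has partial
  correlation 0 (perfect residualization), while a constant input is an
  error.
- Ridge fits with penalty 0 fall back to the pure least-squares solution;
  the penalty grid mode breaks ties toward more regularization.
- The spectrogram floor is applied relative to the maximum; inverting an
  all-silence spectrogram returns silence.

## Known limitations

- The stimulus generator emulates modulation statistics, not phonetics; no
  claim of intelligibility is made, and behavioural/perceptual components
  of the original paradigm are out of scope.
- Electrode anatomy is out of scope; the anatomical inclusion criterion is
  an explicit whitelist (all electrodes, in synthetic mode).
- The real-data path (`preprocess_raw`, `extract_hfb`) is exercised on
  simulated sinusoids, bursts and pulses, not on clinical recordings.
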