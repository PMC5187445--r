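Package: strfshift
Title: Spectrotemporal Receptive Field Plasticity Analysis for Intracranial
    Speech Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for studying rapid shifts in the
    spectrotemporal tuning of human auditory cortex. Provides modulation-domain
    low-pass filtering of speech audio with iterative spectrogram inversion, a
    gammatone auditory spectrogram front end, high-frequency broadband (HFB)
    amplitude extraction from intracranial recordings, ridge-regression
    estimation of ensemble spectrotemporal receptive fields (eSTRFs) with
    leave-one-trial-out jackknife cross-validation, multitaper coherence
    converted to an information rate in bits per second, modulation transfer
    function and partial-correlation tuning contrasts, and sign-flip and
    cluster-based permutation inference. A synthetic-experiment generator with
    known ground-truth receptive fields makes every stage testable without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
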