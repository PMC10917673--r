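Package: ripplecoact
Title: Hippocampal Ripple Detection and Ripple-Locked Coactivity of
    Stimulus-Specific Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for intracranial electrophysiology recorded
    during an associative object-location memory task in a virtual arena.
    Provides bipolar re-referencing and line-noise removal for multichannel
    local field potentials, detection of interictal epileptiform discharges
    and artifact masking, detection of hippocampal ripples (80-140 Hz) with
    envelope and spectral-peak criteria, ripple-triggered analyses (delta
    phase locking, cross-regional ripple coupling, time-frequency power,
    single-unit firing), rank-based memory-performance scoring, surrogate
    based classification of object-tuned and place-tuned neurons, pairwise
    ripple-locked coactivity z-score maps with cluster-based permutation
    inference, and a synthetic-session generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
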