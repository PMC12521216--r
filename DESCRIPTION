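Package: semgretrain
Title: Window-Selection Paradigms for Retraining Inter-Session sEMG Gesture Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements and compares three window-selection paradigms for
    retraining and rejection in inter-session surface-electromyography (sEMG)
    hand-gesture classification: signal-to-noise-ratio Quality Acceptance (QA),
    Edited Nearest Neighbour (ENN) instance selection, and Confidence
    Retraining (CR). Provides the full pre-processing protocol (min-max
    normalisation, 200 ms / 10 ms sliding windows, restimulus-based labelling,
    odd/even repetition train/test split, rest undersampling), the four
    time-domain features (MAV, SSC, ZC, WL) plus a per-window SNR quality
    metric against a clean 1 s rest reference, a batch discriminant and an
    incrementally trainable convolutional classifier, pink-noise augmentation,
    a synthetic multi-session sEMG generator with controllable inter-session
    drift, and the session-by-session train/retrain/test evaluation protocol
    with majority-vote smoothing, confusion/F1 metrics and Wilcoxon
    signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
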