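---
title: "Window selection for retraining inter-session sEMG gesture classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window selection for retraining inter-session sEMG gesture classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgretrain)
```

## The problem

Pattern-recognition control of myoelectric prostheses classifies hand
gestures from multi-channel surface electromyography (sEMG). Within a
single recording session such classifiers can be extremely accurate, but
sEMG is non-stationary: between sessions the electrodes are re-donned and
shift, skin-electrode impedance changes, muscles fatigue, and the limb is
held differently. A classifier frozen after its first session can lose
tens of percentage points of accuracy on the next day's data — often
approaching the 12.5% chance level of the 8-class problem (rest plus seven
grasps).

Retraining on windows from each new session can repair the loss, but not
every window helps: new sessions contain transition windows, contaminated
rest, and noisy segments. This package implements three per-window
*selection paradigms* that decide which windows of a new session enter
retraining (and, symmetrically, which test windows are trusted enough to
be scored):

* **Quality Acceptance (QA)** — keep a window only if its three largest
  per-channel SNRs all exceed 1.8 dB, a purely data-driven quality screen
  that never consults a classifier.
* **Edited Nearest Neighbour (ENN)** — rank all other windows of the new
  session by Euclidean distance in standardised feature space, skip the
  nearest 20 (adjacent overlapping windows are near-copies), let the next
  7 vote with weight $1/d$, and keep the window only if the vote matches
  its true label.
* **Confidence Retraining (CR)** — keep a window only if the current
  classifier's maximum class probability is at least 0.75; retained
  windows keep their true labels (the supervised variant).

## The processing pipeline

Each session is processed identically, in a fixed order:

1. **Min-max normalisation** per channel to $[-1, 1]$. Channels have
   different gains and sessions are processed independently, so the bounds
   are per channel and per session; a constant channel maps to 0.
2. **Sliding windows** of 200 ms advanced by 10 ms, the standard
   real-time segmentation (window width and step are rounded to samples at
   the session's sampling rate).
3. **Labelling** by the majority class of the window's samples. Ties
   involving rest go to rest — conservative for windows straddling an
   activation boundary — and activity-activity ties to the lower class
   index, for determinism. Rest windows inherit the repetition id of the
   nearest following activation (the preceding one at the recording end),
   so the odd/even split is defined everywhere.
4. **Odd/even repetition split**: odd repetitions train, even test. This
   halves the data without temporal leakage between the sets.
5. **Rest undersampling** to the rounded mean of the activity-class
   counts, uniformly without replacement under an explicit seed. Activity
   windows are never removed.
6. **Features and SNR**: per channel, the four time-domain features —
   mean absolute value, slope sign changes, zero crossings, waveform
   length — plus the per-channel SNR
   $10\log_{10}(P_s/P_r)$, where $P_s$ is the window's mean squared
   amplitude and $P_r$ that of the session's *clean rest reference*: the
   central second of the first rest run strictly longer than 2 s. Both
   powers are means, not sums, so the ratio is length-invariant.

One deliberate deviation from the conventional printed form of the feature
table: the zero-crossing indicator is implemented as the standard strict
sign change (0 otherwise), since a formulation that adds 1 in the
"otherwise" branch degenerates to $N-1$ for every window and carries no
information.

The paradigm always sees the *balanced* training set of the new session
(normalise → window → label → split → undersample → select), and the
classifier is then retrained on the accepted windows only.

## Classifiers

Two families are provided, mirroring practice in myoelectric control:

* **Batch discriminant** (`"batch_discriminant"`): a Gaussian linear
  discriminant on the flattened feature vectors. Batch learners need all
  data at once, so the classifier keeps a cumulative pool of everything it
  has been trained on and refits from scratch at each retraining. The
  pooled covariance is shrunk toward $\bar{\sigma}^2 I$ (intensity
  $10^{-4}$, escalated only if the Cholesky factorisation still fails), so
  duplicated or constant feature columns cannot crash a fit. On
  well-conditioned data the posteriors agree with a reference LDA
  implementation to numerical tolerance (this is tested).
* **Incremental convolutional network** (`"incremental_convnet"`): a
  compact temporal conv net on raw windows — two convolution blocks with
  ReLU, global average pooling, dense softmax over the fixed 8-class
  space — trained with Adam at learning rate 0.001 and *continued* on
  accepted new windows only at 0.0001 for retraining. Epoch counts are
  fixed (30 fit, 10 retrain, no early stopping) for reproducibility over
  tuning. The first block's kernel and stride scale with the window width
  so the same architecture applies at any sampling rate. All weights and
  batch orders derive from one root seed, so full protocol runs are
  exactly repeatable.

The class space never shrinks below 8, even when a session's accepted
windows miss a class, keeping confusion matrices comparable across
sessions. Whether retraining should also replay first-session raw windows
is an open design choice for incremental learners; the package retrains on
accepted new windows only, which matches the pure-incremental reading and
keeps the comparison with the batch learner (which *does* accumulate)
informative.

## The evaluation protocol

`run_protocol()` walks the sessions in order: fit on session 1's training
set, test on its test set; for each later session, optionally expose the
balanced training set to the paradigm and retrain on the accepted windows
(`mode = "retrain"`), optionally reject test windows by the same rule
(`mode = "reject"`), or both. Rejection changes only which windows are
scored, never a prediction; if a session's every test window is rejected
its accuracy is reported as missing, not zero — an unresponsive controller
is a reporting problem, not a score.

Streamed predictions can be smoothed by a **majority vote** over the
$2m+1$-window neighbourhood, with $m$ the largest integer whose look-ahead
$m \times \text{step}$ stays within the 100 ms acceptable controller
delay: 21 windows at a 10 ms step. The vote is centred (the bound applies
to neighbours on either side) and shrinks symmetrically at stream edges;
ties fall to the lowest class index.

Metrics are classification accuracy (percent correct), the row-normalised
confusion matrix, per-class and macro F1 (a class absent from both
predictions and labels is scored 0 and flagged), F1 deltas between
sessions, and the paired two-sided Wilcoxon signed-rank test (at
$\alpha = 0.05$) for comparing per-session accuracies against the
no-retraining baseline.

## The synthetic generator

Real multi-session benchmarks are external accessions; the package ships a
generator that emulates their *structure* so every claim can be exercised
end to end on synthetic data:

* per session, `n_reps` repetitions of 7 grasps in order, ~4 s activations
  separated by ~4 s rest at 2 kHz on 14 channels (the defaults);
* activations are band-limited (20 Hz to 0.45 `fs`) amplitude-modulated
  Gaussian noise with a smooth class-specific spatial gain bump around the
  electrode ring, with trapezoidal 0.25 s onset/offset ramps so transition
  windows exist and exercise the labelling rule;
* baseline noise with `noise_sigma = 0.7`, sized against the default gains
  so the strongest channels of an activation sit a few dB above rest — the
  regime real forearm recordings occupy. (With much weaker noise, the
  random asymmetry of each session's min-max extremes becomes visible to
  the zero-crossing feature and acts as a spurious session fingerprint.)
* inter-session drift: per re-donning, channel gains take multiplicative
  log-normal steps, the baseline noise level takes a log-normal step, and
  the spatial patterns are circularly displaced around the ring by a
  fractional number of channels — always at least a little, cumulatively
  across sessions. `drift_scale = 0.4` was calibrated once so that a
  classifier frozen after session 1 loses well over 15 percentage points
  on session 2 on average, the degradation regime reported for real
  day-to-day recordings; `drift_scale = 0` is the control and costs under
  5 points.

What the generator does *not* emulate: motor-unit physiology, power-line
interference, within-session fatigue trends, or the exact SNR statistics
of any real dataset. Passing tests on synthetic data therefore demonstrate
that the algorithms behave as specified under controlled drift, not that
any particular accuracy will be attained on real recordings.

**Pink-noise augmentation** degrades a recording the way the noisier
variant of a benchmark is built: unit-variance $1/f$ noise (spectrally
shaped white noise, slope $\approx -1$ over 1–500 Hz) is generated once
per recording and scaled by the greatest integer $k$ that keeps the
recording's average top-3-channel SNR at or above 1.8 dB; the rest
reference is then re-extracted from the augmented signal, since a deployed
system would only ever see the augmented stream. The average SNR is a
closed quadratic form in $k$, but the chosen $k$ is verified against a
from-scratch scan in the tests.

## Numerical choices and degenerate inputs

* QA compares the *third-largest* SNR with the threshold (all of the top
  three must clear it) and uses a strict inequality; the laxer any-of-three
  reading is exposed as `qa_rule = "any"`. CR uses at-or-above.
* ENN standardises feature columns before distances (waveform length is
  orders of magnitude larger than MAV and would otherwise dominate);
  zero-distance voters are capped at weight $1/10^{-12}$; vote ties fall
  to the lowest class index. The implementation is checked against an
  exhaustive sorted-distance brute force on dozens of random instances.
* All randomness (undersampling, weight initialisation, batch order,
  simulation) fans out from one root seed through a fixed linear map, so
  any result table is bit-reproducible.
* Degenerate inputs error early and informatively: recordings shorter than
  one window, stimulus values outside 0–7, probability rows off the
  simplex, rest references with zero power, ENN with too few windows.

## Desk-scale study sizes

The packaged drift-recovery study (`drift_recovery_study()`, also run by
`scripts/acceptance.R`) uses 10 replicate synthetic subjects with 4
repetitions per grasp, 1.5 s activations, 2.5 s rests at 1 kHz and 14
channels — about 11,000 windows per session before balancing — with the
batch discriminant classifier. These sizes were chosen so a complete
4-arm, 10-session study runs in minutes on a single CPU while leaving
every per-session training set in the thousands of windows; they are the
package's own desk-scale choice, and all structural defaults
(12 repetitions, 4 s/4 s timing, 2 kHz) remain available through
`simulation_config()`.

## A worked run

```{r, eval = FALSE}
cfg <- simulation_config(n_sessions = 3, n_reps = 4, fs = 1000,
                         activation_s = 1.5, rest_s = 2.5, seed = 1)
sessions <- simulate_multisession(cfg)
res_none <- run_protocol(sessions, paradigm = "NONE", mode = "none", seed = 1)
res_enn <- run_protocol(sessions, paradigm = "ENN", mode = "retrain", seed = 1)
cbind(none = as.data.frame(res_none)$accuracy_pct,
      enn = as.data.frame(res_enn)$accuracy_pct)
```

## Known limitations

* ENN-based *test* rejection needs true labels and is therefore an offline
  analysis tool, not an online controller component; the package errors
  rather than silently substituting predicted labels.
* The incremental network is a compact stand-in sized for CPU training;
  it demonstrates the retraining contract (continued training at a reduced
  learning rate), not the ceiling performance of any published
  architecture.
* The MAT reader supports the classic Level-4 numeric layout only; modern
  HDF5-based `.mat` files must be converted or exported to the portable
  TSV + YAML container first.
* Paradigm fusion, unsupervised CR (predicted-label retraining) and
  per-user threshold tuning are out of scope.
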