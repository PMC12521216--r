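# semgretrain

Window-selection paradigms for retraining inter-session sEMG hand-gesture
classifiers.

## What this is for

Surface-electromyography (sEMG) pattern recognition can decode hand
gestures with near-perfect accuracy inside one recording session, yet the
same classifier frozen overnight routinely loses tens of percentage points
the next day: electrodes are re-donned and shift, skin impedance changes,
muscles fatigue. Retraining on data from each new session recovers much of
the loss — but only if the right windows are retrained on. This package is
for researchers in myoelectric control who want to compare, under
controlled and fully reproducible conditions, three per-window selection
rules for retraining and rejection:

* **QA — Quality Acceptance.** A window of the multi-channel signal is
  kept iff its three largest per-channel SNRs all exceed 1.8 dB, where the
  SNR of a window is `10·log10(P_s / P_r)` against the session's clean 1 s
  rest reference (mean-squared powers). Purely signal-driven; no
  classifier involved.
* **ENN — Edited Nearest Neighbour.** All other windows of the new
  session are ranked by Euclidean distance in standardised time-domain
  feature space; the nearest 20 are skipped (10 ms steps on 200 ms windows
  make adjacent windows ≥ 50% copies), the next 7 vote with weight `1/d`,
  and the window is kept iff the vote matches its true label.
* **CR — Confidence Retraining.** A window is kept iff the classifier's
  maximum class probability is ≥ 0.75 (supervised: retained windows keep
  their true labels).

Around the paradigms the package provides the complete experimental
apparatus: min-max normalisation, 200 ms / 10 ms windowing, majority
labelling from the per-sample stimulus vector, odd/even repetition
train/test splitting, rest undersampling, the four time-domain features
(MAV, SSC, ZC, WL), a batch shrinkage-LDA and an incrementally trainable
temporal conv net (Adam, 0.001 → 0.0001 for retraining), pink-noise
(`1/f`) augmentation with greatest-integer scaling against the 1.8 dB
floor, a synthetic multi-session generator with controllable
inter-session drift, majority-vote stream smoothing (21 windows at 10 ms
steps under a 100 ms delay bound), confusion/F1 metrics and paired
Wilcoxon tests.

## A worked example

```r
library(semgretrain)

cfg <- simulation_config(n_sessions = 2, n_reps = 4, fs = 1000,
                         activation_s = 1.5, rest_s = 2.5, seed = 1)
sessions <- simulate_multisession(cfg)

none <- run_protocol(sessions, paradigm = "NONE", mode = "none",    seed = 1)
enn  <- run_protocol(sessions, paradigm = "ENN",  mode = "retrain", seed = 1)
print(none)
#> protocol_result: 2 session(s)
#> session 1: accuracy 85.3%, macro F1 0.874, 2384 test windows used
#> session 2: accuracy 63.3%, macro F1 0.621, 2384 test windows used
print(enn)
#> protocol_result: 2 session(s)
#> session 1: accuracy 85.3%, macro F1 0.874, 2384 test windows used
#> session 2: accuracy 83.7%, macro F1 0.861, 2384 test windows used
```

Session 1 is the within-session baseline. Without retraining, simulated
electrode drift costs ~22 points on session 2; exposing session 2's
balanced training set to the ENN paradigm and retraining on the accepted
windows recovers most of it. `as.data.frame()` turns a result into a
per-session table; `write_results()`, `write_mask()` and
`write_features()` produce tabular text artefacts.

The same experiment runs from a shell:

```sh
Rscript inst/exec/semgretrain run --out out/ --paradigm enn \
    --classifier batch --mode retrain --sessions 2 --reps 4 \
    --fs 1000 --activation 1.5 --rest 2.5 --seed 1
```

Subcommands `simulate`, `preprocess`, `augment` and `report` cover the
rest of the pipeline; see `?cli_run`.

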