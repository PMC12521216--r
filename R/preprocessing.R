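#' Min-max normalise a multi-channel signal to [-1, 1]
#'
#' Maps each channel linearly so that its minimum becomes -1 and its maximum
#' +1, preserving the shape and distribution of the signal while bounding it
#' to a range suitable as classifier input. Normalisation is per channel and
#' per session: channels have different gains and sessions are processed
#' independently. A constant (zero-range) channel maps to 0.
#'
#' @param signal numeric matrix, samples x channels (a vector is treated as
#'   one channel).
#' @return matrix of the same shape with every channel in [-1, 1].
#' @export
minmax_normalise <- function(signal) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1L)
  if (!is.numeric(signal) || nrow(signal) < 1L || ncol(signal) < 1L)
    stopf("signal must be a non-empty numeric matrix")
  if (!all(is.finite(signal)))
    stopf("signal contains non-finite values")
  lo <- apply(signal, 2L, min)
  hi <- apply(signal, 2L, max)
  rng <- hi - lo
  out <- signal
  for (j in seq_len(ncol(signal))) {
    out[, j] <- if (rng[j] == 0) 0 else 2 * (signal[, j] - lo[j]) / rng[j] - 1
  }
  out
}

#' Segment a recording into sliding windows
#'
#' Applies the standard real-time sEMG segmentation: 200 ms window width
#' advanced in 10 ms steps. Window widths and steps are converted to samples
#' by rounding `width_s * fs` and `step_s * fs`. Window `i` (0-based) covers
#' samples `[i*step, i*step + width)`.
#'
#' @param recording a [session_recording()].
#' @param width_s,step_s window width and step in seconds.
#' @param keep_raw keep the raw sample array (`n_windows x width x channels`)?
#'   Set `FALSE` to save memory when only features are needed downstream.
#' @return a `window_set`: a list with elements `raw` (or `NULL`),
#'   `features`, `snr_db`, `labels`, `repetition` (filled by later steps),
#'   `start_sample` (1-based index of each window's first sample), `fs`,
#'   `width_samples`, `step_samples`, `n_windows`, `n_channels`.
#' @export
slide_windows <- function(recording, width_s = 0.200, step_s = 0.010,
                          keep_raw = TRUE) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$fs
  width <- as.integer(round(width_s * fs))
  step <- as.integer(round(step_s * fs))
  n <- nrow(recording$signal)
  nch <- ncol(recording$signal)
  if (width < 1L || step < 1L) stopf("window width and step must be >= 1 sample")
  if (n < width)
    stopf("recording has %d samples; at least one full window (%d) is required", n, width)
  n_win <- (n - width) %/% step + 1L
  starts <- 1L + (seq_len(n_win) - 1L) * step
  raw <- NULL
  if (keep_raw) {
    raw <- array(NA_real_, dim = c(n_win, width, nch))
    idx <- outer(starts, 0L:(width - 1L), `+`)       # n_win x width
    for (ch in seq_len(nch)) {
      raw[, , ch] <- matrix(recording$signal[, ch][idx], nrow = n_win)
    }
  }
  structure(list(
    raw = raw, features = NULL, snr_db = NULL,
    labels = NULL, repetition = NULL,
    start_sample = starts, fs = fs,
    width_samples = width, step_samples = step,
    n_windows = n_win, n_channels = nch
  ), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "window_set: %d windows (%d samples wide, step %d) x %d channels\n",
    x$n_windows, x$width_samples, x$step_samples, x$n_channels))
  if (!is.null(x$labels))
    cat("  label counts:",
        paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                      as.integer(table(x$labels))), collapse = " "), "\n")
  if (!is.null(x$features)) cat("  features computed (MAV, SSC, ZC, WL)\n")
  if (!is.null(x$snr_db)) cat("  per-channel SNRs computed\n")
  invisible(x)
}

# subset a window_set by window index
subset_windows <- function(ws, keep) {
  stopifnot(inherits(ws, "window_set"))
  if (is.logical(keep)) keep <- which(keep)
  out <- ws
  if (!is.null(ws$raw)) out$raw <- ws$raw[keep, , , drop = FALSE]
  if (!is.null(ws$features)) out$features <- ws$features[keep, , , drop = FALSE]
  if (!is.null(ws$snr_db)) out$snr_db <- ws$snr_db[keep, , drop = FALSE]
  if (!is.null(ws$labels)) out$labels <- ws$labels[keep]
  if (!is.null(ws$repetition)) out$repetition <- ws$repetition[keep]
  out$start_sample <- ws$start_sample[keep]
  out$n_windows <- length(keep)
  out
}

#' @export
`[.window_set` <- function(x, i) subset_windows(x, i)

#' Assign a class label to every window
#'
#' Labels each window with the majority class of its samples according to
#' the per-sample stimulus vector. Ties involving rest are broken toward
#' rest (class 0), which is conservative for windows straddling an
#' activation boundary; ties between two activity classes fall to the lower
#' class index for determinism.
#'
#' Each window also receives a repetition id: rest samples inherit the
#' repetition of the nearest following activation sample (or the preceding
#' one at the end of the recording), and the window takes the modal
#' effective repetition of its samples.
#'
#' @param ws a `window_set` from [slide_windows()].
#' @param stimulus per-sample class vector (0..7) covering every window.
#' @param repetition optional per-sample repetition vector; rest samples may
#'   carry 0 and are filled by inheritance as described above.
#' @return the `window_set` with `labels` (and, when `repetition` is given,
#'   window `repetition`) filled in.
#' @export
label_windows <- function(ws, stimulus, repetition = NULL) {
  stopifnot(inherits(ws, "window_set"))
  stimulus <- as.integer(stimulus)
  if (anyNA(stimulus) || any(stimulus < 0L) || any(stimulus > 7L))
    stopf("stimulus values must lie in 0..7")
  need <- max(ws$start_sample) + ws$width_samples - 1L
  if (length(stimulus) < need)
    stopf("stimulus (%d samples) does not cover the last window (needs %d)",
          length(stimulus), need)
  # per-window counts of each value via cumulative sums: rest is column 1,
  # so the "first" tie-break of max.col prefers rest, then lower class ids
  counts <- windowed_value_counts(stimulus, 0:7, ws$start_sample, ws$width_samples)
  ws$labels <- c(0:7)[max.col(counts, ties.method = "first")]
  if (!is.null(repetition)) {
    eff <- effective_repetition(stimulus, as.integer(repetition))
    vals <- sort(unique(eff))
    rc <- windowed_value_counts(eff, vals, ws$start_sample, ws$width_samples)
    ws$repetition <- vals[max.col(rc, ties.method = "first")]
  }
  ws
}

# count occurrences of each value of `vals` inside every window
windowed_value_counts <- function(x, vals, starts, width) {
  counts <- matrix(0, length(starts), length(vals))
  for (j in seq_along(vals)) {
    cs <- c(0, cumsum(x == vals[j]))
    counts[, j] <- cs[starts + width] - cs[starts]
  }
  counts
}

# Per-sample repetition with rest samples inheriting the repetition of the
# nearest following activation sample (preceding one at the recording end).
effective_repetition <- function(stimulus, repetition) {
  n <- length(stimulus)
  eff <- repetition
  act <- stimulus > 0L
  if (!any(act)) return(eff)
  a <- which(act)
  rest <- which(!act)
  # index of the nearest following activation sample (NA after the last)
  pos <- findInterval(rest, a) + 1L
  has_next <- pos <= length(a)
  eff[rest[has_next]] <- repetition[a[pos[has_next]]]
  if (any(!has_next)) {
    # trailing rest: inherit the preceding activation's repetition
    eff[rest[!has_next]] <- repetition[a[length(a)]]
  }
  eff
}

#' Split a window set into train and test by repetition parity
#'
#' Odd repetitions form the training set and even repetitions the testing
#' set, giving a roughly 50:50 split with no information leakage between
#' the two sets.
#'
#' @param ws a labelled `window_set` with window repetition ids.
#' @return list with elements `train` and `test`, both `window_set`s.
#' @export
split_by_repetition <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(ws$repetition))
    stopf("window repetition ids are required; run label_windows() with a repetition vector")
  odd <- ws$repetition %% 2L == 1L
  if (!any(!odd)) warning("no even repetitions: test set is empty")
  if (!any(odd)) warning("no odd repetitions: training set is empty")
  list(train = subset_windows(ws, which(odd)),
       test = subset_windows(ws, which(!odd)))
}

#' Undersample rest windows to the mean activity-class count
#'
#' The 4 s rest between grasps leaves the rest class heavily
#' over-represented. Rest windows are undersampled, uniformly without
#' replacement, down to the rounded mean count of the activity classes
#' present. Activity windows are never touched, and if the rest count is
#' already at or below the target nothing is removed.
#'
#' @param ws a labelled `window_set`.
#' @param seed RNG seed for the uniform draw (default 0 for reproducibility).
#' @return the `window_set` with rest windows reduced to the target count.
#' @export
undersample_rest <- function(ws, seed = 0L) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(ws$labels)) stopf("windows must be labelled first")
  act_counts <- table(ws$labels[ws$labels > 0L])
  if (length(act_counts) == 0L)
    stopf("no activity windows present; cannot derive an undersampling target")
  target <- as.integer(round(mean(act_counts)))
  rest_idx <- which(ws$labels == 0L)
  if (length(rest_idx) <= target) return(ws)
  keep_rest <- with_seed(seed, sort(sample(rest_idx, target)))
  subset_windows(ws, sort(c(which(ws$labels > 0L), keep_rest)))
}

#' Run the full per-session pre-processing pipeline
#'
#' Normalise, window, label, split odd/even by repetition, undersample rest
#' in both splits, then compute time-domain features and per-channel SNRs
#' against the session's clean rest reference. This is the fixed order in
#' which a session enters the retraining protocol: the paradigm always sees
#' the already balanced training set.
#'
#' @param recording a [session_recording()].
#' @param seed seed for the rest undersampling.
#' @param keep_raw keep raw window samples (needed by the convolutional
#'   classifier; feature-based classifiers can drop them).
#' @return list with `train` and `test` `window_set`s (features and SNRs
#'   filled) and `ref`, the session's [extract_rest_reference()] output.
#' @export
prepare_session <- function(recording, seed = 0L, keep_raw = FALSE) {
  stopifnot(inherits(recording, "session_recording"))
  norm <- recording
  norm$signal <- minmax_normalise(recording$signal)
  ref <- extract_rest_reference(norm)
  ws <- slide_windows(norm, keep_raw = keep_raw)
  ws <- label_windows(ws, norm$stimulus, norm$repetition)
  ws <- window_features(ws, signal = norm$signal)
  ws <- window_set_snr(ws, ref, signal = norm$signal)
  sp <- split_by_repetition(ws)
  list(train = undersample_rest(sp$train, seed = seed),
       test = undersample_rest(sp$test, seed = fan_seed(seed, 1L)),
       ref = ref)
}
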