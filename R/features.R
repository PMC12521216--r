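#' Time-domain features of one window
#'
#' Computes the four classic time-domain sEMG features per channel:
#'
#' * MAV, mean absolute value: `sum(|x_i|) / N`;
#' * SSC, slope sign changes: the number of interior samples that are strict
#'   local extrema (strictly greater than both neighbours, or strictly less);
#' * ZC, zero crossings: the number of strict sign changes between
#'   consecutive samples (a sample equal to zero does not count);
#' * WL, waveform length: `sum(|x_{i+1} - x_i|)`.
#'
#' @param window numeric matrix, samples x channels (a vector is one
#'   channel). At least 3 samples are required (SSC needs interior samples).
#' @return numeric matrix `channels x 4` with columns MAV, SSC, ZC, WL.
#' @export
td_features <- function(window) {
  if (is.null(dim(window))) window <- matrix(window, ncol = 1L)
  n <- nrow(window)
  if (n < 3L) stopf("a window needs at least 3 samples (got %d)", n)
  mav <- colMeans(abs(window))
  x0 <- window[-n, , drop = FALSE]
  x1 <- window[-1L, , drop = FALSE]
  wl <- colSums(abs(x1 - x0))
  zc <- colSums((x0 > 0 & x1 < 0) | (x0 < 0 & x1 > 0))
  mid <- window[2:(n - 1L), , drop = FALSE]
  lo <- window[1:(n - 2L), , drop = FALSE]
  hi <- window[3:n, , drop = FALSE]
  ssc <- colSums((mid > lo & mid > hi) | (mid < lo & mid < hi))
  out <- cbind(MAV = mav, SSC = ssc, ZC = zc, WL = wl)
  rownames(out) <- NULL
  out
}

#' Compute time-domain features for every window of a window set
#'
#' Vectorised over windows: fills `ws$features` with an array
#' `n_windows x n_channels x 4` (MAV, SSC, ZC, WL). Works from the raw
#' window array when present, otherwise from the session signal.
#'
#' @param ws a `window_set`.
#' @param signal the session signal matrix (required when `ws$raw` is NULL).
#' @return the `window_set` with `features` filled.
#' @export
window_features <- function(ws, signal = NULL) {
  stopifnot(inherits(ws, "window_set"))
  feat <- array(NA_real_, dim = c(ws$n_windows, ws$n_channels, 4L),
                dimnames = list(NULL, NULL, c("MAV", "SSC", "ZC", "WL")))
  st <- ws$start_sample
  wd <- ws$width_samples
  if (is.null(ws$raw) && !is.null(signal)) {
    # every feature is a windowed sum of a per-sample (or per-gap/triplet)
    # quantity, so cumulative sums give all windows in one O(n) pass
    for (ch in seq_len(ws$n_channels)) {
      x <- signal[, ch]
      n <- length(x)
      cs_abs <- c(0, cumsum(abs(x)))
      feat[, ch, 1L] <- (cs_abs[st + wd] - cs_abs[st]) / wd
      dx <- diff(x)                                  # gap i: samples i, i+1
      cs_wl <- c(0, cumsum(abs(dx)))
      feat[, ch, 4L] <- cs_wl[st + wd - 1L] - cs_wl[st]
      zc <- (x[-n] > 0 & x[-1L] < 0) | (x[-n] < 0 & x[-1L] > 0)
      cs_zc <- c(0, cumsum(zc))
      feat[, ch, 3L] <- cs_zc[st + wd - 1L] - cs_zc[st]
      mid <- x[2:(n - 1L)]; lo <- x[1:(n - 2L)]; hi <- x[3:n]
      ssc <- (mid > lo & mid > hi) | (mid < lo & mid < hi)   # centre i+1
      cs_ssc <- c(0, cumsum(ssc))
      feat[, ch, 2L] <- cs_ssc[st + wd - 2L] - cs_ssc[st]
    }
  } else {
    for (ch in seq_len(ws$n_channels)) {
      w <- channel_windows(ws, signal, ch)      # n_windows x width
      n <- ncol(w)
      x0 <- w[, -n, drop = FALSE]
      x1 <- w[, -1L, drop = FALSE]
      feat[, ch, 1L] <- rowMeans(abs(w))
      mid <- w[, 2:(n - 1L), drop = FALSE]
      lo <- w[, 1:(n - 2L), drop = FALSE]
      hi <- w[, 3:n, drop = FALSE]
      feat[, ch, 2L] <- rowSums((mid > lo & mid > hi) | (mid < lo & mid < hi))
      feat[, ch, 3L] <- rowSums((x0 > 0 & x1 < 0) | (x0 < 0 & x1 > 0))
      feat[, ch, 4L] <- rowSums(abs(x1 - x0))
    }
  }
  ws$features <- feat
  ws
}

# windows of one channel as an n_windows x width matrix
channel_windows <- function(ws, signal, ch) {
  if (!is.null(ws$raw)) return(ws$raw[, , ch])
  if (is.null(signal))
    stopf("window_set carries no raw samples; supply the session signal")
  idx <- outer(ws$start_sample, 0L:(ws$width_samples - 1L), `+`)
  matrix(signal[, ch][idx], nrow = ws$n_windows)
}

# flatten the feature array to n_windows x (channels*4) for classifiers
flatten_features <- function(ws) {
  stopifnot(!is.null(ws$features))
  d <- dim(ws$features)
  matrix(ws$features, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Extract the clean 1 s rest reference of a recording
#'
#' Scans the stimulus vector for rest runs strictly longer than 2 s and
#' takes the central 1 s of the first qualifying run as the session's clean
#' rest segment. Its per-channel mean squared amplitude is the reference
#' power P_r of the SNR quality metric; one reference is extracted per
#' recording and reused for every window of that session.
#'
#' @param recording a [session_recording()].
#' @return a `rest_reference`: list with `segment` (round(fs) x channels),
#'   `power_per_channel`, and `source_interval` (first and last sample,
#'   1-based).
#' @export
extract_rest_reference <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$fs
  r <- rle(recording$stimulus == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths > 2 * fs)
  if (length(qual) == 0L)
    stopf("no clean rest: recording has no rest run longer than 2 s")
  k <- qual[1L]
  seg_len <- as.integer(round(fs))
  seg_start <- starts[k] + (r$lengths[k] - seg_len) %/% 2L
  seg <- recording$signal[seg_start:(seg_start + seg_len - 1L), , drop = FALSE]
  structure(list(
    segment = seg,
    power_per_channel = colMeans(seg^2),
    source_interval = c(seg_start, seg_start + seg_len - 1L)
  ), class = "rest_reference")
}

#' @export
print.rest_reference <- function(x, ...) {
  cat(sprintf(
    "rest_reference: samples %d-%d, %d channels, rest power %.3g-%.3g\n",
    x$source_interval[1], x$source_interval[2], ncol(x$segment),
    min(x$power_per_channel), max(x$power_per_channel)))
  invisible(x)
}

#' Per-channel SNR of one window against a rest reference
#'
#' The signal-to-noise ratio quality metric: `10 * log10(P_s / P_r)` per
#' channel, with P_s the window's mean squared amplitude and P_r the rest
#' reference's. Both powers are means, not sums, so windows and the 1 s
#' reference are comparable despite different lengths.
#'
#' @param window numeric matrix, samples x channels.
#' @param ref a [extract_rest_reference()] result with strictly positive
#'   power on every channel.
#' @return numeric vector of per-channel SNRs in dB.
#' @export
window_snr <- function(window, ref) {
  if (is.null(dim(window))) window <- matrix(window, ncol = 1L)
  stopifnot(inherits(ref, "rest_reference"))
  pr <- ref$power_per_channel
  if (any(pr <= 0))
    stopf("degenerate rest reference: zero power on channel(s) %s",
          paste(which(pr <= 0), collapse = ", "))
  if (ncol(window) != length(pr))
    stopf("window has %d channels but reference has %d", ncol(window), length(pr))
  10 * log10(colMeans(window^2) / pr)
}

#' Per-channel SNRs for every window of a window set
#'
#' @param ws a `window_set`.
#' @param ref the session's rest reference.
#' @param signal the session signal (required when `ws$raw` is NULL).
#' @return the `window_set` with `snr_db` (`n_windows x n_channels`) filled.
#' @export
window_set_snr <- function(ws, ref, signal = NULL) {
  stopifnot(inherits(ws, "window_set"), inherits(ref, "rest_reference"))
  pr <- ref$power_per_channel
  if (any(pr <= 0)) stopf("degenerate rest reference: zero power on a channel")
  if (length(pr) != ws$n_channels)
    stopf("reference channel count (%d) does not match windows (%d)",
          length(pr), ws$n_channels)
  snr <- matrix(NA_real_, ws$n_windows, ws$n_channels)
  st <- ws$start_sample
  wd <- ws$width_samples
  for (ch in seq_len(ws$n_channels)) {
    ps <- if (is.null(ws$raw) && !is.null(signal)) {
      cs <- c(0, cumsum(signal[, ch]^2))
      (cs[st + wd] - cs[st]) / wd
    } else {
      rowMeans(channel_windows(ws, signal, ch)^2)
    }
    snr[, ch] <- 10 * log10(ps / pr[ch])
  }
  ws$snr_db <- snr
  ws
}

#' Write a feature table to a tab-separated file
#'
#' One row per window with `(channel, feature)` columns named
#' `ch<i>_<MAV|SSC|ZC|WL>`, plus the window label and repetition when
#' present.
#'
#' @param ws a `window_set` with features computed.
#' @param path output file path.
#' @export
write_features <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"), !is.null(ws$features))
  mat <- flatten_features(ws)
  colnames(mat) <- as.vector(outer(
    paste0("ch", seq_len(ws$n_channels)), c("MAV", "SSC", "ZC", "WL"),
    function(a, b) paste0(a, "_", b)))
  tab <- data.table::as.data.table(mat)
  if (!is.null(ws$labels)) tab[, label := ws$labels]
  if (!is.null(ws$repetition)) tab[, repetition := ws$repetition]
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
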