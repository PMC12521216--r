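#' Configuration for the synthetic multi-session sEMG generator
#'
#' The generator emulates the structure of a DB6-style acquisition: per
#' session, `n_reps` repetitions of 7 grasp classes performed in order,
#' each ~`activation_s` seconds of muscle activity separated by ~`rest_s`
#' seconds of rest, recorded on `n_channels` electrodes at `fs` Hz.
#' Activations are band-limited amplitude-modulated Gaussian noise with
#' class-specific spatial gain patterns across the electrode ring;
#' sessions beyond the first drift: channel gains take multiplicative
#' log-normal steps, the baseline noise level wanders, and the spatial
#' patterns are circularly displaced around the ring by a fractional
#' number of channels, cumulatively across sessions (emulating electrode
#' displacement and impedance change between donning sessions).
#'
#' @param n_sessions number of sessions (default 10).
#' @param n_reps repetitions of each grasp per session (default 12).
#' @param fs sampling rate in Hz (default 2000).
#' @param n_channels electrode count (default 14).
#' @param activation_s,rest_s activation and rest durations in seconds
#'   (defaults 4 and 4).
#' @param class_pattern_gain 7 x `n_channels` matrix of spatial gains; the
#'   default places a smooth bump per class around the electrode ring.
#' @param drift_scale per-session drift magnitude (>= 0; 0 disables drift).
#'   The default (0.4) is calibrated so a classifier fixed after session 1
#'   loses substantial accuracy on session 2, the phenomenon the retraining
#'   paradigms exist to repair.
#' @param noise_sigma baseline (rest) noise standard deviation. The
#'   default (0.7) is sized against the default activation gains so the
#'   strongest channels of an activation sit a few dB above rest, the
#'   regime real forearm recordings occupy.
#' @param ramp_s trapezoidal onset/offset ramp of each activation, so
#'   transition windows straddling an activation boundary exist.
#' @param seed root RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_sessions = 10L, n_reps = 12L, fs = 2000,
                              n_channels = 14L, activation_s = 4,
                              rest_s = 4, class_pattern_gain = NULL,
                              drift_scale = 0.4, noise_sigma = 0.7,
                              ramp_s = 0.25, seed = 0L) {
  if (activation_s <= 0 || rest_s <= 0 || fs <= 0) stopf("durations and fs must be > 0")
  if (drift_scale < 0) stopf("drift_scale must be >= 0")
  if (noise_sigma <= 0) stopf("noise_sigma must be > 0")
  if (is.null(class_pattern_gain))
    class_pattern_gain <- default_class_patterns(n_channels)
  class_pattern_gain <- as.matrix(class_pattern_gain)
  if (nrow(class_pattern_gain) != 7L || ncol(class_pattern_gain) != n_channels)
    stopf("class_pattern_gain must be 7 x n_channels")
  structure(list(
    n_sessions = as.integer(n_sessions), n_reps = as.integer(n_reps),
    fs = fs, n_channels = as.integer(n_channels),
    activation_s = activation_s, rest_s = rest_s,
    class_pattern_gain = class_pattern_gain,
    drift_scale = drift_scale, noise_sigma = noise_sigma,
    ramp_s = ramp_s, seed = as.integer(seed)
  ), class = "simulation_config")
}

# circularly shift spatial patterns by a fractional number of channels
# (linear interpolation around the ring); models electrode displacement
shift_patterns <- function(patterns, delta) {
  nch <- ncol(patterns)
  pos <- (seq_len(nch) - 1L - delta) %% nch
  i0 <- floor(pos)
  f <- pos - i0
  i0 <- (i0 %% nch) + 1L
  i1 <- (i0 %% nch) + 1L
  sweep(patterns[, i0, drop = FALSE], 2L, 1 - f, `*`) +
    sweep(patterns[, i1, drop = FALSE], 2L, f, `*`)
}

# smooth per-class spatial bumps around the electrode ring
default_class_patterns <- function(n_channels) {
  centres <- (seq_len(7L) - 1L) * n_channels / 7
  ch <- seq_len(n_channels) - 1L
  pat <- matrix(0, 7L, n_channels)
  for (c_ in 1:7) {
    d <- pmin(abs(ch - centres[c_]), n_channels - abs(ch - centres[c_]))
    pat[c_, ] <- 0.15 + (0.8 + 0.1 * c_) * exp(-(d / 1.8)^2)
  }
  pat
}

#' Generate pink (1/f) noise
#'
#' Spectrally shaped white Gaussian noise: the FFT of a white sequence is
#' multiplied by a `1/sqrt(f)` amplitude filter (DC removed) and inverted,
#' giving a power spectral density sloping as approximately `1/f`. Each
#' channel is independent, zero-mean and normalised to unit variance.
#'
#' @param n_samples samples per channel (>= 2).
#' @param n_channels number of independent channels.
#' @param seed RNG seed; the same seed reproduces the noise bit-exactly.
#' @return numeric matrix `n_samples x n_channels`.
#' @export
pink_noise <- function(n_samples, n_channels = 1L, seed = 0L) {
  if (!is_count(n_samples) || n_samples < 2L) stopf("n_samples must be >= 2")
  k <- seq_len(n_samples) - 1L
  f <- pmin(k, n_samples - k)                 # symmetric frequency index
  h <- ifelse(f == 0, 0, 1 / sqrt(f))
  out <- with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
    apply(x, 2L, function(col) Re(stats::fft(stats::fft(col) * h, inverse = TRUE)) / n_samples)
  })
  out <- sweep(out, 2L, colMeans(out))
  sweep(out, 2L, apply(out, 2L, stats::sd), `/`)
}

#' Fit the log-log spectral slope of a signal
#'
#' Least-squares slope of log10(periodogram power) against log10(frequency)
#' over a frequency band; pink noise fits close to -1.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param band two-element frequency band in Hz (default 1-500).
#' @return the fitted slope.
#' @export
spectral_slope <- function(x, fs, band = c(1, 500)) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1L) * fs / n
  idx <- freq >= band[1] & freq <= band[2]
  unname(stats::coef(stats::lm(log10(sp[idx]) ~ log10(freq[idx])))[2])
}

#' Simulate a multi-session sEMG dataset
#'
#' Produces `n_sessions` [session_recording()]s per the structure described
#' in [simulation_config()]. The stimulus vector marks the full activation
#' plateau of each grasp (0 during rest) and the repetition vector carries
#' the repetition id during activations (0 at rest), exactly the layout of
#' the restimulus / rerepetition vectors the pre-processing consumes.
#'
#' @param cfg a [simulation_config()].
#' @param subject_id subject identifier attached to every session.
#' @return list of `n_sessions` [session_recording()]s.
#' @export
simulate_multisession <- function(cfg = simulation_config(), subject_id = 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  gains <- rep(1, cfg$n_channels)
  sigma <- cfg$noise_sigma
  patterns <- cfg$class_pattern_gain
  out <- vector("list", cfg$n_sessions)
  for (s in seq_len(cfg$n_sessions)) {
    if (s > 1L && cfg$drift_scale > 0) {
      drift <- with_seed(fan_seed(cfg$seed, 1000L + s), {
        list(gain_step = exp(stats::rnorm(cfg$n_channels, sd = cfg$drift_scale)),
             sigma_step = exp(stats::rnorm(1L, sd = cfg$drift_scale / 2)),
             # every re-donning displaces the electrode ring at least a
             # little; displacement in channels, cumulative over sessions
             shift = cfg$drift_scale * 2 * (0.6 + 0.4 * abs(stats::rnorm(1L))) *
               sign(stats::rnorm(1L)))
      })
      gains <- gains * drift$gain_step
      sigma <- sigma * drift$sigma_step
      patterns <- shift_patterns(patterns, drift$shift)
    }
    out[[s]] <- simulate_session(cfg, s, gains, sigma, patterns,
                                 seed = fan_seed(cfg$seed, s),
                                 subject_id = subject_id)
  }
  out
}

simulate_session <- function(cfg, session_id, gains, sigma, patterns, seed,
                             subject_id = 1L) {
  fs <- cfg$fs
  act_n <- as.integer(round(cfg$activation_s * fs))
  rest_n <- as.integer(round(cfg$rest_s * fs))
  ramp_n <- min(as.integer(round(cfg$ramp_s * fs)), act_n %/% 3L)
  cycle <- rest_n + act_n
  n <- rest_n + cfg$n_reps * 7L * cycle       # leading rest, then grasp cycles
  stimulus <- integer(n)
  repetition <- integer(n)
  envelope <- numeric(n)
  class_at <- integer(n)                       # class driving the envelope
  pos <- rest_n
  for (rep_i in seq_len(cfg$n_reps)) {
    for (cl in 1:7) {
      a0 <- pos + 1L
      a1 <- pos + act_n
      stimulus[a0:a1] <- cl
      repetition[a0:a1] <- rep_i
      env <- rep(1, act_n)
      if (ramp_n > 0L) {
        env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
        env[(act_n - ramp_n + 1L):act_n] <- seq(1, 0, length.out = ramp_n)
      }
      envelope[a0:a1] <- env
      class_at[a0:a1] <- cl
      pos <- pos + cycle
    }
  }
  band <- c(20, 0.45 * fs) / (fs / 2)
  bf <- signal::butter(4, pmin(band, c(0.95, 0.99)), type = "pass")
  signal_mat <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * cfg$n_channels), n, cfg$n_channels)
    # per-repetition amplitude variability, as humans never repeat exactly
    amp_jitter <- matrix(stats::rnorm(cfg$n_reps * 7L, 1, 0.08),
                         cfg$n_reps, 7L)
    for (ch in seq_len(cfg$n_channels)) {
      carrier <- as.numeric(signal::filtfilt(bf, m[, ch]))
      carrier <- carrier / stats::sd(carrier)
      amp <- numeric(n)
      act <- class_at > 0L
      amp[act] <- patterns[class_at[act], ch] *
        amp_jitter[cbind(repetition[act], class_at[act])]
      m[, ch] <- gains[ch] * (carrier * envelope * amp +
                                sigma * stats::rnorm(n))
    }
    m
  })
  session_recording(signal_mat, fs = fs, stimulus = stimulus,
                    repetition = repetition, session_id = session_id,
                    subject_id = subject_id)
}

#' Average top-channel SNR of a recording
#'
#' The scalar quality summary used by the augmentation search: each window's
#' `top` largest per-channel SNRs (against the recording's own clean rest
#' reference) are averaged, and the result is averaged over all windows.
#'
#' @param recording a [session_recording()].
#' @param top number of largest per-channel SNRs averaged per window.
#' @return mean SNR in dB.
#' @export
average_top_snr <- function(recording, top = 3L) {
  ref <- extract_rest_reference(recording)
  ws <- slide_windows(recording, keep_raw = FALSE)
  ws <- window_set_snr(ws, ref, signal = recording$signal)
  mean(apply(ws$snr_db, 1L, function(r) mean(sort(r, decreasing = TRUE)[seq_len(top)])))
}

#' Degrade a recording with integer-scaled pink noise
#'
#' Adds `k` times a unit-variance pink-noise realisation to the recording,
#' where `k` is the greatest integer that does not bring the recording's
#' average SNR (see [average_top_snr()]) below the 1.8 dB quality
#' threshold. The noise is generated once and scaled — never regenerated
#' per candidate `k`. If even `k = 1` breaches the threshold the recording
#' is returned unchanged (`k = 0`). The rest reference downstream consumers
#' use must be re-extracted from the augmented signal, which is what a
#' deployed system would observe.
#'
#' @param recording a [session_recording()].
#' @param seed seed for the pink-noise realisation.
#' @param snr_floor_db quality threshold in dB (default 1.8).
#' @param top number of top channels in the average-SNR summary.
#' @param k_max safety cap on the search.
#' @return the augmented [session_recording()] with attributes
#'   `noise_scale` (the chosen `k`) and `average_snr_db`.
#' @export
augment_session <- function(recording, seed = 0L, snr_floor_db = 1.8,
                            top = 3L, k_max = 10000L) {
  stopifnot(inherits(recording, "session_recording"))
  noise <- pink_noise(nrow(recording$signal), ncol(recording$signal), seed = seed)
  # SNR of the augmented signal is a closed form in k: window and reference
  # powers are quadratics mean((x + k u)^2) = Px + 2k Pxu + k^2 Pu
  ref0 <- extract_rest_reference(recording)
  ws <- slide_windows(recording, keep_raw = FALSE)
  terms_win <- power_terms(ws, recording$signal, noise)
  ri <- ref0$source_interval
  seg <- ri[1]:ri[2]
  pr_x <- colMeans(recording$signal[seg, , drop = FALSE]^2)
  pr_u <- colMeans(noise[seg, , drop = FALSE]^2)
  pr_xu <- colMeans(recording$signal[seg, , drop = FALSE] * noise[seg, , drop = FALSE])
  avg_snr_at <- function(k) {
    ps <- terms_win$x + 2 * k * terms_win$xu + k^2 * terms_win$u
    pr <- pr_x + 2 * k * pr_xu + k^2 * pr_u
    snr <- 10 * log10(sweep(ps, 2L, pr, `/`))
    mean(apply(snr, 1L, function(r) mean(sort(r, decreasing = TRUE)[seq_len(top)])))
  }
  if (avg_snr_at(0) < snr_floor_db) {
    k <- 0L
  } else {
    k <- 0L
    while (k < k_max && avg_snr_at(k + 1L) >= snr_floor_db) k <- k + 1L
  }
  out <- recording
  if (k > 0L) out$signal <- recording$signal + k * noise
  attr(out, "noise_scale") <- k
  attr(out, "average_snr_db") <- avg_snr_at(k)
  out
}

# per-window, per-channel power cross-terms of signal x and noise u
power_terms <- function(ws, x, u) {
  nch <- ncol(x)
  px <- pu <- pxu <- matrix(NA_real_, ws$n_windows, nch)
  idx <- outer(ws$start_sample, 0L:(ws$width_samples - 1L), `+`)
  for (ch in seq_len(nch)) {
    xw <- matrix(x[, ch][idx], nrow = ws$n_windows)
    uw <- matrix(u[, ch][idx], nrow = ws$n_windows)
    px[, ch] <- rowMeans(xw^2)
    pu[, ch] <- rowMeans(uw^2)
    pxu[, ch] <- rowMeans(xw * uw)
  }
  list(x = px, u = pu, xu = pxu)
}
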