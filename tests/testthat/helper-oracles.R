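# Independent oracles and tiny fixtures shared across the suite.
# Oracles are deliberately naive (scalar loops, exhaustive scans) so they
# check the vectorised implementations through a different route.

# scalar-loop time-domain features of a single channel
oracle_td_channel <- function(x) {
  n <- length(x)
  mav <- 0
  for (v in x) mav <- mav + abs(v)
  mav <- mav / n
  wl <- 0
  for (i in 1:(n - 1)) wl <- wl + abs(x[i + 1] - x[i])
  zc <- 0
  for (i in 1:(n - 1)) {
    if ((x[i] > 0 && x[i + 1] < 0) || (x[i] < 0 && x[i + 1] > 0)) zc <- zc + 1
  }
  ssc <- 0
  for (i in 2:(n - 1)) {
    if ((x[i] > x[i - 1] && x[i] > x[i + 1]) ||
        (x[i] < x[i - 1] && x[i] < x[i + 1])) ssc <- ssc + 1
  }
  c(MAV = mav, SSC = ssc, ZC = zc, WL = wl)
}

# exhaustive sorted-distance ENN: rank every other point, skip, vote 1/d
oracle_enn <- function(features, labels, skip = 20L, vote_k = 7L,
                       standardise = TRUE) {
  if (standardise) {
    mu <- colMeans(features)
    sd_ <- apply(features, 2, sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    features <- scale(features, mu, sd_)
  }
  n <- nrow(features)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j == i) next
      d[j] <- sqrt(sum((features[i, ] - features[j, ])^2))
    }
    ord <- order(d, na.last = TRUE)
    voters <- ord[(skip + 1):(skip + vote_k)]
    v <- numeric(8)
    for (j in voters) {
      v[labels[j] + 1] <- v[labels[j] + 1] + 1 / max(d[j], 1e-12)
    }
    keep[i] <- (which.max(v) - 1) == labels[i]
  }
  keep
}

# a miniature labelled recording with deterministic structure:
# rest / class-1 / rest / class-2 / ... with given durations
tiny_recording <- function(fs = 100, classes = c(1, 2), act_s = 1,
                           rest_s = 3, n_channels = 2, reps = 1,
                           amp = 1, sigma = 0.1, seed = 7) {
  act_n <- round(act_s * fs)
  rest_n <- round(rest_s * fs)
  n <- rest_n + reps * length(classes) * (act_n + rest_n)
  stimulus <- integer(n)
  repetition <- integer(n)
  pos <- rest_n
  for (r in seq_len(reps)) {
    for (cl in classes) {
      stimulus[(pos + 1):(pos + act_n)] <- cl
      repetition[(pos + 1):(pos + act_n)] <- r
      pos <- pos + act_n + rest_n
    }
  }
  set.seed(seed)
  sig <- matrix(rnorm(n * n_channels, sd = sigma), n, n_channels)
  env <- ifelse(stimulus > 0, amp, 0)
  for (ch in seq_len(n_channels)) {
    sig[, ch] <- sig[, ch] + env * rnorm(n) * (1 + 0.3 * ch)
  }
  session_recording(sig, fs = fs, stimulus = stimulus,
                    repetition = repetition)
}

# bind two n x width x channels arrays along the first axis
abind_first <- function(a, b) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# two well-separated Gaussian clouds in feature space, 8-class label space
gaussian_clouds <- function(n_per = 200, d = 4, sep = 6, classes = c(1L, 2L),
                            seed = 11) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(k) {
    matrix(rnorm(n_per * d, mean = sep * (k - 1)), n_per, d)
  }))
  list(x = x, labels = rep(classes, each = n_per))
}
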