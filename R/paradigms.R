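#' Configuration of the window-selection paradigms
#'
#' Bundles every tunable threshold of the three selection paradigms:
#'
#' * `cr_threshold`: Confidence Retraining keeps a window when the
#'   classifier's maximum class probability is at or above this value
#'   (default 0.75, which also guarantees the other 7 classes sum to at
#'   most 25%).
#' * `snr_threshold_db`, `snr_top_channels`: Quality Acceptance keeps a
#'   window when its `snr_top_channels` largest per-channel SNRs all lie
#'   strictly above `snr_threshold_db` (defaults 1.8 dB and 3; electrodes
#'   sit around the forearm, so only a few face the active muscle).
#' * `enn_vote_k`, `enn_skip`: Edited Nearest Neighbour votes with
#'   neighbours `enn_skip + 1` through `enn_skip + enn_vote_k` (defaults 20
#'   and 7, i.e. neighbours 21-27). With a 10 ms step on 200 ms windows the
#'   10 adjacent windows on either side share at least 50% of their
#'   samples, so the nearest 20 neighbours are excluded to avoid the vote
#'   trivially echoing the window itself.
#' * `qa_rule`: `"all"` (default) requires all of the top channels above
#'   threshold; `"any"` is the laxer alternative reading.
#'
#' @param cr_threshold probability in \[0, 1\].
#' @param snr_threshold_db SNR threshold in dB (strict inequality).
#' @param snr_top_channels number of largest per-channel SNRs compared.
#' @param enn_vote_k number of voting neighbours.
#' @param enn_skip number of nearest neighbours excluded before voting.
#' @param distance distance metric for ENN (only `"euclidean"`).
#' @param qa_rule aggregation over the top channels, `"all"` or `"any"`.
#' @return a `selection_config` list.
#' @export
selection_config <- function(cr_threshold = 0.75, snr_threshold_db = 1.8,
                             snr_top_channels = 3L, enn_vote_k = 7L,
                             enn_skip = 20L, distance = "euclidean",
                             qa_rule = c("all", "any")) {
  qa_rule <- match.arg(qa_rule)
  distance <- match.arg(distance, "euclidean")
  if (cr_threshold < 0 || cr_threshold > 1) stopf("cr_threshold must lie in [0, 1]")
  if (!is_count(enn_vote_k) || enn_vote_k < 1L) stopf("enn_vote_k must be >= 1")
  if (!is_count(enn_skip)) stopf("enn_skip must be >= 0")
  if (!is_count(snr_top_channels) || snr_top_channels < 1L)
    stopf("snr_top_channels must be >= 1")
  structure(list(
    cr_threshold = cr_threshold, snr_threshold_db = snr_threshold_db,
    snr_top_channels = as.integer(snr_top_channels),
    enn_vote_k = as.integer(enn_vote_k), enn_skip = as.integer(enn_skip),
    distance = distance, qa_rule = qa_rule
  ), class = "selection_config")
}

new_selection_mask <- function(keep, paradigm, labels = NULL, score = NULL,
                               cfg = NULL) {
  retention <- rep(NA_real_, 8L)
  if (!is.null(labels)) {
    for (cl in 0:7) {
      idx <- labels == cl
      if (any(idx)) retention[cl + 1L] <- 100 * mean(keep[idx])
    }
  }
  structure(list(
    keep = keep, paradigm = paradigm,
    retention_per_class = retention, score = score, config = cfg
  ), class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask [%s]: %d / %d windows kept (%.1f%%)\n",
              x$paradigm, sum(x$keep), length(x$keep),
              100 * mean(x$keep)))
  if (!all(is.na(x$retention_per_class)))
    cat("  retention per class (%):",
        paste(sprintf("%d:%.0f", 0:7, x$retention_per_class), collapse = " "), "\n")
  invisible(x)
}

#' Quality Acceptance window selection
#'
#' Keeps a window if and only if its `snr_top_channels` largest per-channel
#' SNRs are all strictly above `snr_threshold_db` (equivalently, its
#' third-largest SNR exceeds the threshold under the defaults). A purely
#' data-driven paradigm: no classifier is consulted.
#'
#' @param snr_db numeric matrix, windows x channels, SNRs in dB.
#' @param cfg a [selection_config()].
#' @param labels optional true labels, used only to report per-class
#'   retention.
#' @return a `selection_mask`.
#' @export
qa_select <- function(snr_db, cfg = selection_config(), labels = NULL) {
  snr_db <- as.matrix(snr_db)
  k <- cfg$snr_top_channels
  if (ncol(snr_db) < k)
    stopf("need at least %d channels for the top-%d SNR rule", k, k)
  topk <- t(apply(snr_db, 1L, function(r) sort(r, decreasing = TRUE)[seq_len(k)]))
  if (k == 1L) topk <- matrix(topk, ncol = 1L)
  keep <- if (cfg$qa_rule == "all") {
    topk[, k] > cfg$snr_threshold_db          # k-th largest above threshold
  } else {
    topk[, 1L] > cfg$snr_threshold_db
  }
  new_selection_mask(keep, "QA", labels, score = topk[, k], cfg = cfg)
}

#' Edited Nearest Neighbour window selection
#'
#' For each window, all other windows are ranked by Euclidean distance in
#' standardised feature space; the nearest `enn_skip` are excluded (they
#' are near-copies produced by the overlapping windows) and the next
#' `enn_vote_k` vote with weight `1/d` for their own class. The window is
#' kept if and only if the class with the maximum accumulated weight equals
#' its true label. Zero-distance voters (duplicate feature vectors) are
#' capped at weight `1/1e-12` so that closer still dominates; vote ties
#' fall to the lowest class index.
#'
#' @param features numeric matrix, windows x feature-dimensions (flattened
#'   time-domain features, channels x 4 per window).
#' @param labels integer true labels in 0..7, one per window.
#' @param cfg a [selection_config()].
#' @param standardise z-score the feature columns before distances are
#'   computed (constant columns become 0)?
#' @return a `selection_mask`.
#' @export
enn_select <- function(features, labels, cfg = selection_config(),
                       standardise = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n) stopf("one label per window required")
  if (n <= cfg$enn_skip + cfg$enn_vote_k)
    stopf("ENN needs more than enn_skip + enn_vote_k = %d windows (got %d)",
          cfg$enn_skip + cfg$enn_vote_k, n)
  if (standardise) features <- standardise_columns(features)
  # full pairwise Euclidean distances; n is the (already balanced) session
  # training set, small enough for the dense matrix
  d2 <- as.matrix(stats::dist(features))
  keep <- logical(n)
  votes <- numeric(n)
  lab1 <- labels + 1L
  rng <- cfg$enn_skip + seq_len(cfg$enn_vote_k)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    voters <- order(di)[rng]
    w <- 1 / pmax(di[voters], 1e-12)
    v <- numeric(8L)
    vl <- lab1[-i][voters]
    for (j in seq_along(voters)) v[vl[j]] <- v[vl[j]] + w[j]
    expected <- argmax_first(v) - 1L
    keep[i] <- expected == labels[i]
    votes[i] <- expected
  }
  new_selection_mask(keep, "ENN", labels, score = votes, cfg = cfg)
}

standardise_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  scale(x, center = mu, scale = sd)[, , drop = FALSE]
}

#' Confidence Retraining window selection
#'
#' Keeps a window if and only if the classifier's maximum class probability
#' for it is at or above `cr_threshold`. This is the supervised variant:
#' retained windows keep their true labels rather than the classifier's
#' predictions.
#'
#' @param probabilities numeric matrix, windows x 8, rows on the
#'   probability simplex (validated to `1e-6`).
#' @param labels true labels in 0..7 (carried through for retraining and
#'   per-class retention reporting).
#' @param cfg a [selection_config()].
#' @return a `selection_mask`.
#' @export
cr_select <- function(probabilities, labels = NULL, cfg = selection_config()) {
  p <- as.matrix(probabilities)
  if (ncol(p) != 8L) stopf("probabilities must have 8 columns (got %d)", ncol(p))
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6))
    stopf("malformed probability rows: entries must be >= 0 and sum to 1")
  maxp <- apply(p, 1L, max)
  keep <- maxp >= cfg$cr_threshold
  new_selection_mask(keep, "CR", labels, score = maxp, cfg = cfg)
}

#' Apply a paradigm's acceptance rule to a test set (rejection)
#'
#' The same decision rules used to select retraining windows can reject
#' test windows: rejected windows are excluded from the performance
#' metrics (in an online system, rejection leaves the current motor output
#' unchanged). `aux` supplies what each paradigm needs: `snr_db` for QA,
#' `probabilities` for CR, and `features` plus `labels` for ENN (whose
#' rejection is inherently supervised — it compares the neighbourhood vote
#' with the true label).
#'
#' @param paradigm one of `"QA"`, `"ENN"`, `"CR"`, `"NONE"`.
#' @param aux named list of paradigm inputs (see above).
#' @param cfg a [selection_config()].
#' @param n_windows number of test windows (required for `"NONE"`, which
#'   keeps everything; otherwise inferred).
#' @return a `selection_mask` over the test windows.
#' @export
reject_test <- function(paradigm, aux = list(), cfg = selection_config(),
                        n_windows = NULL) {
  paradigm <- match.arg(paradigm, c("QA", "ENN", "CR", "NONE"))
  switch(paradigm,
    NONE = {
      if (is.null(n_windows)) {
        n_windows <- nrow(aux$snr_db %||% aux$probabilities %||% aux$features)
      }
      if (is.null(n_windows)) stopf("n_windows required for paradigm NONE")
      new_selection_mask(rep(TRUE, n_windows), "NONE", aux$labels, cfg = cfg)
    },
    QA = {
      if (is.null(aux$snr_db)) stopf("QA rejection needs aux$snr_db")
      qa_select(aux$snr_db, cfg, labels = aux$labels)
    },
    CR = {
      if (is.null(aux$probabilities)) stopf("CR rejection needs aux$probabilities")
      cr_select(aux$probabilities, labels = aux$labels, cfg = cfg)
    },
    ENN = {
      if (is.null(aux$features)) stopf("ENN rejection needs aux$features")
      if (is.null(aux$labels))
        stopf("ENN rejection needs true labels: it is a supervised rule")
      enn_select(aux$features, aux$labels, cfg)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a selection mask to a tab-separated file
#'
#' One row per window: index, keep flag, paradigm, and the score the
#' decision was based on (third-largest SNR for QA, vote class for ENN,
#' maximum probability for CR).
#'
#' @param mask a `selection_mask`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "selection_mask"))
  tab <- data.table::data.table(
    window = seq_along(mask$keep), keep = mask$keep,
    paradigm = mask$paradigm,
    score = if (is.null(mask$score)) NA_real_ else mask$score)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
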