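#' Classification metrics for an 8-class gesture problem
#'
#' Accuracy (percentage of correct classifications), the row-normalised
#' confusion matrix in percent (rows of absent classes are all zero), the
#' per-class F1 score and its unweighted (macro) mean. A class absent from
#' both predictions and labels has no defined F1; it is reported as 0 and
#' flagged in the `undefined_f1` attribute.
#'
#' @param preds,labels integer vectors in 0..7 of equal length.
#' @return list with `accuracy_pct`, `confusion` (8 x 8, rows in %),
#'   `f1_per_class` (length 8), `macro_f1`.
#' @export
classification_metrics <- function(preds, labels) {
  preds <- as.integer(preds); labels <- as.integer(labels)
  if (length(preds) != length(labels))
    stopf("preds (%d) and labels (%d) differ in length", length(preds), length(labels))
  if (any(c(preds, labels) < 0L | c(preds, labels) > 7L))
    stopf("classes must lie in 0..7")
  n <- length(labels)
  counts <- matrix(0, 8L, 8L, dimnames = list(true = 0:7, pred = 0:7))
  for (i in seq_len(n)) counts[labels[i] + 1L, preds[i] + 1L] <-
      counts[labels[i] + 1L, preds[i] + 1L] + 1
  rs <- rowSums(counts)
  confusion <- counts
  confusion[rs > 0, ] <- 100 * counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  f1 <- numeric(8L)
  undefined <- logical(8L)
  for (k in 1:8) {
    tp <- counts[k, k]
    fp <- sum(counts[-k, k])
    fn <- sum(counts[k, -k])
    if (tp + fp + fn == 0) { f1[k] <- 0; undefined[k] <- TRUE }
    else f1[k] <- 2 * tp / (2 * tp + fp + fn)
  }
  out <- list(accuracy_pct = 100 * mean(preds == labels),
              confusion = confusion, f1_per_class = f1,
              macro_f1 = mean(f1))
  attr(out$f1_per_class, "undefined_f1") <- undefined
  out
}

#' Majority-vote smoothing of a streamed prediction sequence
#'
#' Each prediction is replaced by the modal class of its symmetric
#' neighbourhood of `2m + 1` windows, with `m` the largest integer whose
#' look-ahead `m * step_ms` stays within the acceptable controller delay
#' (`delay_ms`, conventionally 100 ms). With a 10 ms step this gives the
#' standard 21-window vote. At the stream edges the neighbourhood shrinks
#' symmetrically; ties fall to the lowest class index.
#'
#' @param pred_stream integer vector of streamed class predictions, in
#'   temporal order.
#' @param step_ms window step in milliseconds (> 0).
#' @param delay_ms acceptable delay bound in milliseconds.
#' @return smoothed integer vector of the same length.
#' @export
majority_vote <- function(pred_stream, step_ms = 10, delay_ms = 100) {
  if (step_ms <= 0) stopf("step_ms must be > 0")
  n <- length(pred_stream)
  if (n == 0L) return(integer(0))
  m <- majority_vote_m(step_ms, delay_ms)
  if (m == 0L) return(pred_stream)
  out <- pred_stream
  for (i in seq_len(n)) {
    r <- min(m, i - 1L, n - i)
    out[i] <- mode_lowest(pred_stream[(i - r):(i + r)])
  }
  out
}

#' @rdname majority_vote
#' @return `majority_vote_m` returns the per-side neighbour count `m`
#'   (so the vote spans `2 * m + 1` windows).
#' @export
majority_vote_m <- function(step_ms = 10, delay_ms = 100) {
  as.integer(floor(delay_ms / step_ms))
}

#' Per-class F1 change between two session results
#'
#' Elementwise `F1(later) - F1(earlier)`; negative entries mean the class
#' scores lower in the later session.
#'
#' @param result_a,result_b two [classification_metrics()] results or
#'   `session_result`s (earlier, later).
#' @return list with `delta_per_class` (length 8) and `macro_delta`.
#' @export
f1_delta <- function(result_a, result_b) {
  list(delta_per_class = result_b$f1_per_class - result_a$f1_per_class,
       macro_delta = result_b$macro_f1 - result_a$macro_f1)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test of `a` vs `b` (differences `a - b`), the standard
#' non-parametric choice for comparing paired per-session accuracies.
#' Significance is conventionally judged at alpha = 0.05. If every
#' difference is zero the test is degenerate; `p = 1` is returned with a
#' warning.
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @param exact passed to [stats::wilcox.test()].
#' @return list with `statistic` (V, the sum of positive signed ranks) and
#'   `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact = NULL) {
  if (length(a) != length(b)) stopf("a and b must be paired (equal length)")
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                       exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

new_session_result <- function(session_id, metrics_, retention, rejection_pct,
                               n_test_used) {
  structure(list(
    session_id = session_id,
    accuracy_pct = metrics_$accuracy_pct,
    confusion = metrics_$confusion,
    f1_per_class = metrics_$f1_per_class,
    macro_f1 = metrics_$macro_f1,
    retention_pct = retention,
    rejection_pct = rejection_pct,
    n_test_windows_used = n_test_used
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("session %d: accuracy %.1f%%, macro F1 %.3f, %d test windows used",
              x$session_id,
              if (is.na(x$accuracy_pct)) NA else x$accuracy_pct,
              x$macro_f1, x$n_test_windows_used))
  if (!is.na(x$rejection_pct)) cat(sprintf(", rejection %.1f%%", x$rejection_pct))
  cat("\n")
  invisible(x)
}

#' Run the session-by-session retraining and testing protocol
#'
#' Session 1: fit the classifier on the session-1 training set and test on
#' the session-1 test set. Every later session `s`: in modes `retrain` and
#' `both`, expose the (balanced) session-`s` training set to the paradigm
#' and retrain the classifier on the accepted windows; then test on the
#' session-`s` test set, excluding windows the paradigm rejects in modes
#' `reject` and `both`. Mode `none` never retrains and never rejects.
#' Rejection changes only which test windows enter the metrics, never the
#' predictions themselves. If every test window of a session is rejected,
#' accuracy is reported as `NA` with a warning (an unresponsive controller
#' is a reporting problem, not a score of zero).
#'
#' @param sessions list of [session_recording()]s, or of prepared sessions
#'   from [prepare_session()] (all preprocessed identically).
#' @param paradigm `"QA"`, `"ENN"`, `"CR"` or `"NONE"` (accept everything).
#' @param classifier_kind `"batch_discriminant"` or `"incremental_convnet"`.
#' @param mode one of `"none"`, `"retrain"`, `"reject"`, `"both"`.
#' @param cfg a [selection_config()].
#' @param seed root seed (undersampling, classifier init, batch order).
#' @param apply_majority_vote smooth each session's prediction stream with
#'   [majority_vote()] before scoring?
#' @return list of `session_result`s, in session order, with the fitted
#'   classifier attached as attribute `classifier`.
#' @export
run_protocol <- function(sessions, paradigm = c("NONE", "QA", "ENN", "CR"),
                         classifier_kind = c("batch_discriminant", "incremental_convnet"),
                         mode = c("none", "retrain", "reject", "both"),
                         cfg = selection_config(), seed = 0L,
                         apply_majority_vote = FALSE) {
  paradigm <- match.arg(paradigm)
  classifier_kind <- match.arg(classifier_kind)
  mode <- match.arg(mode)
  if (length(sessions) < 1L) stopf("at least one session is required")
  keep_raw <- classifier_kind == "incremental_convnet"
  prep <- lapply(seq_along(sessions), function(s) {
    x <- sessions[[s]]
    if (inherits(x, "session_recording"))
      prepare_session(x, seed = fan_seed(seed, 10L + s), keep_raw = keep_raw)
    else x
  })
  clf <- semg_classifier(classifier_kind, seed = fan_seed(seed, 1L))
  results <- vector("list", length(prep))
  for (s in seq_along(prep)) {
    train <- prep[[s]]$train
    test <- prep[[s]]$test
    retention <- rep(NA_real_, 8L)
    if (s == 1L) {
      clf <- fit_classifier(clf, classifier_input(clf, train), train$labels)
    } else if (mode %in% c("retrain", "both")) {
      mask <- select_for_paradigm(paradigm, clf, train, cfg)
      retention <- mask$retention_per_class
      clf <- retrain_classifier(clf,
                                classifier_input(clf, train, mask$keep),
                                train$labels[mask$keep])
    }
    keep_test <- rep(TRUE, test$n_windows)
    rejection_pct <- NA_real_
    if (mode %in% c("reject", "both") && paradigm != "NONE") {
      rmask <- select_for_paradigm(paradigm, clf, test, cfg)
      keep_test <- rmask$keep
      rejection_pct <- 100 * mean(!keep_test)
    }
    preds <- predict_class(clf, classifier_input(clf, test))
    if (apply_majority_vote) {
      step_ms <- 1000 * test$step_samples / test$fs
      preds <- majority_vote(preds, step_ms = step_ms)
    }
    if (!any(keep_test)) {
      warning(sprintf("session %d: every test window rejected; accuracy undefined", s))
      met <- list(accuracy_pct = NA_real_,
                  confusion = matrix(0, 8L, 8L),
                  f1_per_class = rep(NA_real_, 8L), macro_f1 = NA_real_)
    } else {
      met <- classification_metrics(preds[keep_test], test$labels[keep_test])
    }
    results[[s]] <- new_session_result(s, met, retention, rejection_pct,
                                       sum(keep_test))
  }
  attr(results, "classifier") <- clf
  class(results) <- "protocol_result"
  results
}

classifier_input <- function(clf, ws, keep = NULL) {
  if (clf$kind == "batch_discriminant") {
    x <- flatten_features(ws)
    if (!is.null(keep)) x <- x[keep, , drop = FALSE]
    x
  } else {
    if (is.null(ws$raw))
      stopf("the convolutional classifier needs raw windows; prepare sessions with keep_raw = TRUE")
    if (is.null(keep)) ws$raw else ws$raw[keep, , , drop = FALSE]
  }
}

select_for_paradigm <- function(paradigm, clf, ws, cfg) {
  switch(paradigm,
    NONE = new_selection_mask(rep(TRUE, ws$n_windows), "NONE", ws$labels, cfg = cfg),
    QA = qa_select(ws$snr_db, cfg, labels = ws$labels),
    ENN = enn_select(flatten_features(ws), ws$labels, cfg),
    CR = cr_select(predict_proba(clf, classifier_input(clf, ws)),
                   labels = ws$labels, cfg = cfg))
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("protocol_result: %d session(s)\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

#' Tabulate a protocol result
#'
#' @param x a `protocol_result` from [run_protocol()].
#' @param ... unused.
#' @return data.frame with one row per session: accuracy, macro F1,
#'   rejection rate and test-window count.
#' @export
as.data.frame.protocol_result <- function(x, ...) {
  data.frame(
    session = vapply(x, `[[`, 0, "session_id"),
    accuracy_pct = vapply(x, `[[`, 0, "accuracy_pct"),
    macro_f1 = vapply(x, `[[`, 0, "macro_f1"),
    rejection_pct = vapply(x, `[[`, 0, "rejection_pct"),
    n_test_windows_used = vapply(x, `[[`, 0, "n_test_windows_used"))
}

#' Drift-recovery benchmark on synthetic multi-session data
#'
#' Repeated end-to-end experiment quantifying how much accuracy a fixed
#' classifier loses across drifting sessions and how much each paradigm
#' recovers through retraining. For each seed, one synthetic multi-session
#' dataset is generated and the protocol is run once per requested
#' paradigm/mode combination with the batch discriminant classifier.
#'
#' @param n_seeds number of independent replicate datasets.
#' @param n_sessions sessions per dataset.
#' @param paradigms character vector of paradigms to run in mode
#'   `"retrain"` (mode `"none"` is always run as the baseline).
#' @param sim_args named list of overrides for [simulation_config()]; the
#'   defaults here are the package's desk-scale study size (4 repetitions,
#'   1.5 s activations, 2.5 s rests at 1 kHz).
#' @param seed root seed; replicate `i` uses a seed fanned out from it.
#' @param classifier_kind classifier to use (batch discriminant by default).
#' @return data.frame with one row per seed x arm x session:
#'   columns `seed`, `arm` (`"none"` or the paradigm), `session`,
#'   `accuracy_pct`.
#' @export
drift_recovery_study <- function(n_seeds = 10L, n_sessions = 2L,
                                 paradigms = character(0),
                                 sim_args = list(), seed = 0L,
                                 classifier_kind = "batch_discriminant") {
  base_args <- list(n_sessions = n_sessions, n_reps = 4L, fs = 1000,
                    activation_s = 1.5, rest_s = 2.5)
  base_args[names(sim_args)] <- sim_args
  rows <- list()
  for (i in seq_len(n_seeds)) {
    rseed <- fan_seed(seed, i)
    cfg <- do.call(simulation_config, c(base_args, list(seed = rseed)))
    sessions <- simulate_multisession(cfg)
    prep <- lapply(seq_along(sessions), function(s)
      prepare_session(sessions[[s]], seed = fan_seed(rseed, 10L + s),
                      keep_raw = classifier_kind == "incremental_convnet"))
    arms <- c(list(c("NONE", "none")),
              lapply(paradigms, function(p) c(p, "retrain")))
    for (arm in arms) {
      res <- run_protocol(prep, paradigm = arm[1], classifier_kind,
                          mode = arm[2], seed = rseed)
      acc <- vapply(res, `[[`, 0, "accuracy_pct")
      rows[[length(rows) + 1L]] <- data.frame(
        seed = i, arm = if (arm[2] == "none") "none" else arm[1],
        session = seq_along(acc), accuracy_pct = acc)
    }
  }
  do.call(rbind, rows)
}

#' Write protocol results as a tabular text file
#'
#' One row per session with accuracy, macro F1, rejection rate, per-class
#' retention and test-window count, prefixed by the experiment identifiers.
#'
#' @param results a `protocol_result`.
#' @param path output path.
#' @param meta named list of identifying columns (subject, paradigm, ...)
#'   repeated on every row.
#' @export
write_results <- function(results, path, meta = list()) {
  tab <- as.data.frame(results)
  for (nm in rev(names(meta))) tab <- cbind(stats::setNames(
    data.frame(rep(meta[[nm]], nrow(tab))), nm), tab)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
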