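test_that("metrics match hand-computed accuracy, confusion and F1", {
  labels <- c(0, 0, 1, 1, 1, 2)
  preds <- c(0, 1, 1, 1, 0, 2)
  m <- classification_metrics(preds, labels)
  expect_equal(m$accuracy_pct, 100 * 4 / 6)
  expect_equal(m$confusion[1, 1:2], c(50, 50), ignore_attr = TRUE)
  expect_equal(m$confusion[2, 1:2], c(100 / 3, 200 / 3), ignore_attr = TRUE)
  expect_equal(rowSums(m$confusion)[1:3], rep(100, 3), ignore_attr = TRUE)
  expect_equal(rowSums(m$confusion)[4:8], rep(0, 5), ignore_attr = TRUE)
  # class with TP=3, FP=1, FN=1 would give F1 = 0.75; build it explicitly
  lab2 <- c(1, 1, 1, 1, 0, 0, 0)
  prd2 <- c(1, 1, 1, 0, 1, 0, 0)
  expect_equal(classification_metrics(prd2, lab2)$f1_per_class[2], 0.75)
  # perfect agreement
  mp <- classification_metrics(0:7, 0:7)
  expect_equal(mp$accuracy_pct, 100)
  expect_equal(diag(mp$confusion), rep(100, 8), ignore_attr = TRUE)
  expect_equal(mp$f1_per_class, rep(1, 8), ignore_attr = TRUE)
  expect_equal(mp$macro_f1, 1)
  expect_error(classification_metrics(1:3, 1:4), "length")
})

test_that("random predictions on balanced 8-class labels approach 12.5%", {
  set.seed(61)
  n <- 80000
  labels <- rep(0:7, each = n / 8)
  preds <- sample(0:7, n, replace = TRUE)
  acc <- classification_metrics(preds, labels)$accuracy_pct
  expect_equal(acc, 12.5, tolerance = 0.05)
})

test_that("absent-class F1 is zero and flagged", {
  m <- classification_metrics(c(0, 1), c(0, 1))
  expect_equal(m$f1_per_class[3:8], rep(0, 6), ignore_attr = TRUE)
  expect_true(all(attr(m$f1_per_class, "undefined_f1")[3:8]))
  expect_false(any(attr(m$f1_per_class, "undefined_f1")[1:2]))
})

test_that("majority vote uses a 21-window neighbourhood at 10 ms steps", {
  expect_equal(majority_vote_m(10, 100), 10L)     # 2*10 + 1 = 21 neighbours
  expect_equal(majority_vote_m(35, 100), 2L)      # m*step <= delay, floor
  # constant stream unchanged
  expect_equal(majority_vote(rep(3L, 50)), rep(3L, 50))
  # a single flipped prediction inside a long run is corrected
  x <- rep(2L, 41); x[21] <- 6L
  expect_equal(majority_vote(x), rep(2L, 41))
  # m = 0 (step larger than delay) is the identity
  x2 <- sample(0:7, 30, replace = TRUE)
  expect_identical(majority_vote(x2, step_ms = 150), x2)
  # three distinct classes in one neighbourhood: tie falls to lowest class
  expect_equal(majority_vote(c(5L, 1L, 3L), step_ms = 100), c(5L, 1L, 3L))
  expect_equal(majority_vote(integer(0)), integer(0))
  expect_error(majority_vote(1:3, step_ms = 0), "step_ms")
})

test_that("f1_delta is elementwise and antisymmetric", {
  a <- classification_metrics(c(0, 1, 2, 2), c(0, 1, 2, 2))
  b <- classification_metrics(c(0, 1, 2, 0), c(0, 1, 2, 2))
  d <- f1_delta(a, b)
  expect_equal(f1_delta(a, a)$delta_per_class, rep(0, 8), ignore_attr = TRUE)
  expect_equal(d$delta_per_class, -f1_delta(b, a)$delta_per_class)
  # only classes 0 and 2 changed
  expect_true(all(d$delta_per_class[c(2, 4:8)] == 0))
  expect_lt(d$delta_per_class[3], 0)
  expect_equal(d$macro_delta, b$macro_f1 - a$macro_f1)
})

test_that("Wilcoxon signed-rank matches a worked small-sample example", {
  # n = 10 pairs with distinct absolute differences 4,-2,6,1,-3,5,7,-9,8,10
  a <- c(14, 8, 16, 11, 7, 15, 17, 1, 18, 20)
  b <- rep(10, 10)
  d <- a - b
  # exhaustive signed-rank oracle: V = sum of ranks of positive differences
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  out <- wilcoxon_signed_rank(a, b)
  expect_equal(out$statistic, V)
  # exact two-sided p by full enumeration of sign assignments
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vdist <- signs %*% rk
  p_exact <- mean(vdist >= max(V, sum(rk) - V)) + mean(vdist <= min(V, sum(rk) - V))
  expect_equal(out$p_value, p_exact, tolerance = 1e-10)
  # symmetry and degenerate case
  expect_equal(wilcoxon_signed_rank(b, a)$p_value, out$p_value)
  expect_warning(same <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(same$p_value, 1)
})

test_that("protocol runs one session without retraining events", {
  rec <- tiny_recording(fs = 200, classes = 1:7, act_s = 0.8, rest_s = 2.2,
                        reps = 2, sigma = 0.4)
  res <- run_protocol(list(rec), paradigm = "NONE", mode = "none", seed = 1)
  expect_length(res, 1)
  expect_s3_class(res[[1]], "session_result")
  expect_equal(attr(res, "classifier")$retrain_count, 0L)
  expect_error(run_protocol(list(rec), mode = "flying"), "arg")
})

test_that("an accept-everything paradigm equals retraining on the full set", {
  cfg <- simulation_config(n_sessions = 2, n_reps = 2, fs = 250,
                           activation_s = 1, rest_s = 2.2, n_channels = 6,
                           seed = 62)
  prep <- lapply(simulate_multisession(cfg), prepare_session, seed = 5)
  res_none_mask <- run_protocol(prep, paradigm = "NONE", mode = "retrain",
                                seed = 3)
  # manual retrain on the full session-2 training set
  clf <- fit_classifier(semg_classifier(seed = semgretrain:::fan_seed(3, 1)),
                        semgretrain:::flatten_features(prep[[1]]$train),
                        prep[[1]]$train$labels)
  clf <- retrain_classifier(clf,
                            semgretrain:::flatten_features(prep[[2]]$train),
                            prep[[2]]$train$labels)
  preds <- predict_class(clf, semgretrain:::flatten_features(prep[[2]]$test))
  want <- classification_metrics(preds, prep[[2]]$test$labels)$accuracy_pct
  expect_equal(res_none_mask[[2]]$accuracy_pct, want)
})

test_that("rejection changes the support set, not the predictions", {
  cfg <- simulation_config(n_sessions = 2, n_reps = 2, fs = 250,
                           activation_s = 1, rest_s = 2.2, n_channels = 6,
                           seed = 63)
  prep <- lapply(simulate_multisession(cfg), prepare_session, seed = 5)
  plain <- run_protocol(prep, paradigm = "QA", mode = "retrain", seed = 3)
  rej <- run_protocol(prep, paradigm = "QA", mode = "both", seed = 3)
  expect_lte(rej[[2]]$n_test_windows_used, plain[[2]]$n_test_windows_used)
  expect_gte(rej[[2]]$rejection_pct, 0)
  # QA keeps exactly the windows its mask says; recompute independently
  mask <- qa_select(prep[[2]]$test$snr_db)
  expect_equal(rej[[2]]$n_test_windows_used, sum(mask$keep))
})

test_that("protocol is deterministic for a fixed root seed", {
  cfg <- simulation_config(n_sessions = 2, n_reps = 2, fs = 250,
                           activation_s = 1, rest_s = 2.2, n_channels = 6,
                           seed = 64)
  sessions <- simulate_multisession(cfg)
  r1 <- run_protocol(sessions, paradigm = "CR", mode = "both", seed = 7)
  r2 <- run_protocol(sessions, paradigm = "CR", mode = "both", seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
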