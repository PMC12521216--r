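test_that("min-max normalisation maps channel extremes to -1/+1", {
  expect_equal(as.vector(minmax_normalise(c(0, 5, 10))), c(-1, 0, 1))
  expect_equal(as.vector(minmax_normalise(c(-2, 0, 2))), c(-1, 0, 1))
  # degenerate constant channel maps to 0, not NaN
  expect_equal(as.vector(minmax_normalise(c(3, 3, 3))), c(0, 0, 0))
  # channels are scaled independently
  two <- minmax_normalise(cbind(c(0, 5, 10), c(10, 20, 40)))
  expect_equal(two[, 1], c(-1, 0, 1))
  expect_equal(two[, 2], c(-1, -1 / 3, 1))
  expect_error(minmax_normalise(matrix(numeric(0), 0, 1)), "non-empty")
  expect_error(minmax_normalise(c(1, NA, 3)), "finite")
})

test_that("normalisation is idempotent and order-preserving", {
  set.seed(3)
  x <- matrix(rnorm(500), 100, 5)
  once <- minmax_normalise(x)
  expect_equal(minmax_normalise(once), once)
  for (j in 1:5) expect_equal(order(once[, j]), order(x[, j]))
  expect_true(all(once >= -1 & once <= 1))
})

test_that("sliding windows follow the closed-form count at 200 ms / 10 ms", {
  rec <- function(n, fs) session_recording(matrix(rnorm(n), ncol = 1), fs,
                                           integer(n), integer(n))
  expect_equal(slide_windows(rec(400, 2000))$n_windows, 1L)
  expect_equal(slide_windows(rec(2000, 2000))$n_windows, 81L)
  expect_error(slide_windows(rec(399, 2000)), "at least one full window")
  # arbitrary (n, fs) against the closed form
  set.seed(5)
  for (i in 1:20) {
    fs <- sample(c(100, 250, 500, 1000, 2000), 1)
    width <- round(0.2 * fs); step <- round(0.01 * fs)
    n <- width + sample(0:5000, 1)
    ws <- slide_windows(rec(n, fs))
    expect_equal(ws$n_windows, (n - width) %/% step + 1L)
    expect_equal(ws$width_samples, width)
    expect_equal(unique(diff(ws$start_sample)), step)
  }
})

test_that("raw window extraction covers [i*step, i*step + width)", {
  n <- 1000; fs <- 500
  rec <- session_recording(matrix(seq_len(n), ncol = 1), fs,
                           integer(n), integer(n))
  ws <- slide_windows(rec)
  expect_equal(dim(ws$raw), c(ws$n_windows, 100, 1))
  for (i in c(1, 7, ws$n_windows)) {
    s <- (i - 1) * ws$step_samples + 1
    expect_equal(as.vector(ws$raw[i, , 1]), s:(s + 99))
  }
})

test_that("window labelling follows the majority rule with rest-biased ties", {
  fs <- 100
  n <- 400
  stim <- integer(n)
  stim[101:200] <- 3L                         # exactly one full window of class 3
  rec <- session_recording(matrix(rnorm(n), ncol = 1), fs, stim, integer(n))
  ws <- slide_windows(rec)
  lab <- label_windows(ws, stim)              # 20-sample windows, 1-sample step
  # window fully inside the class-3 activation
  full_idx <- which(ws$start_sample == 101)
  expect_equal(lab$labels[full_idx], 3L)
  # 60/40 majority goes to the activity class
  w6040 <- which(ws$start_sample == 189)      # samples 189..208: 12 class-3, 8 rest
  expect_equal(lab$labels[w6040], 3L)
  # exact 50/50 tie is broken toward rest
  half <- which(ws$start_sample == 191)       # samples 191..210: 10 class-3, 10 rest
  expect_equal(lab$labels[half], 0L)
  expect_error(label_windows(ws, stim + 9L), "0..7")
})

test_that("rest windows inherit the following activation's repetition", {
  fs <- 100
  rec <- tiny_recording(fs = fs, classes = c(1, 2), act_s = 1, rest_s = 3,
                        reps = 2)
  ws <- slide_windows(rec)
  ws <- label_windows(ws, rec$stimulus, rec$repetition)
  # rest windows before the first activation belong to repetition 1
  first_act <- min(which(rec$stimulus > 0))
  early <- ws$start_sample + ws$width_samples - 1 < first_act
  expect_true(all(ws$repetition[early] == 1L))
  # trailing rest inherits the last activation's repetition
  expect_equal(ws$repetition[ws$n_windows], max(rec$repetition))
  # every activation window carries its own repetition
  idx <- which(ws$labels > 0)
  for (i in idx[c(1, length(idx))]) {
    span <- ws$start_sample[i]:(ws$start_sample[i] + ws$width_samples - 1)
    expect_true(ws$repetition[i] %in% rec$repetition[span])
  }
})

test_that("repetition split is an odd/even partition", {
  rec <- tiny_recording(classes = 1:3, reps = 4, act_s = 0.5, rest_s = 1)
  ws <- label_windows(slide_windows(rec), rec$stimulus, rec$repetition)
  sp <- split_by_repetition(ws)
  expect_equal(sp$train$n_windows + sp$test$n_windows, ws$n_windows)
  expect_true(all(sp$train$repetition %% 2 == 1))
  expect_true(all(sp$test$repetition %% 2 == 0))
  # random repetition vectors: counts always partition
  set.seed(9)
  for (i in 1:10) {
    ws2 <- ws
    ws2$repetition <- sample(1:12, ws$n_windows, replace = TRUE)
    sp2 <- split_by_repetition(ws2)
    expect_equal(sp2$train$n_windows + sp2$test$n_windows, ws$n_windows)
  }
  # single odd repetition leaves the test set empty, with a warning
  ws3 <- ws
  ws3$repetition <- rep(1L, ws$n_windows)
  expect_warning(sp3 <- split_by_repetition(ws3), "test set is empty")
  expect_equal(sp3$test$n_windows, 0L)
})

test_that("rest undersampling hits the mean activity count and is seeded", {
  mk <- function(counts) {
    # counts: named vector class -> count; build a label-only window_set
    rec <- tiny_recording(classes = 1, reps = 1)
    ws <- label_windows(slide_windows(rec), rec$stimulus, rec$repetition)
    labels <- unlist(mapply(function(cl, k) rep(cl, k),
                            as.integer(names(counts)), counts))
    n <- length(labels)
    ws$labels <- as.integer(labels)
    ws$repetition <- rep(1L, n)
    ws$start_sample <- seq_len(n)
    ws$n_windows <- n
    ws$raw <- NULL
    ws
  }
  ws <- mk(c(`0` = 700, `1` = 100, `2` = 100, `3` = 100, `4` = 100,
             `5` = 100, `6` = 100, `7` = 100))
  out <- undersample_rest(ws, seed = 1)
  expect_equal(sum(out$labels == 0), 100L)
  expect_equal(table(out$labels[out$labels > 0]), table(ws$labels[ws$labels > 0]))
  # non-uniform activity counts: target is the rounded mean
  ws2 <- mk(c(`0` = 500, `1` = 80, `2` = 120, `3` = 100, `4` = 100,
              `5` = 100, `6` = 100, `7` = 100))
  expect_equal(sum(undersample_rest(ws2, seed = 1)$labels == 0), 100L)
  # rest below target is left alone
  ws3 <- mk(c(`0` = 50, `1` = 100, `2` = 100))
  expect_equal(sum(undersample_rest(ws3, seed = 1)$labels == 0), 50L)
  # deterministic for a fixed seed; activity windows never removed
  a <- undersample_rest(ws, seed = 42)
  b <- undersample_rest(ws, seed = 42)
  expect_identical(a$start_sample, b$start_sample)
  expect_equal(sum(a$labels > 0), sum(ws$labels > 0))
})

test_that("prepare_session yields balanced, feature-complete splits", {
  rec <- tiny_recording(fs = 200, classes = 1:7, act_s = 0.8, rest_s = 2.2,
                        reps = 2, sigma = 0.4)
  prep <- prepare_session(rec, seed = 1)
  for (part in list(prep$train, prep$test)) {
    expect_false(is.null(part$features))
    expect_false(is.null(part$snr_db))
    expect_true(all(is.finite(part$features)))
    counts <- table(part$labels)
    expect_lte(counts["0"], round(mean(counts[names(counts) != "0"])) + 1)
  }
  expect_true(all(prep$train$repetition %% 2 == 1))
  expect_true(all(prep$test$repetition %% 2 == 0))
})
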