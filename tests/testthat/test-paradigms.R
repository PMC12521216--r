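test_that("QA keeps a window only when all top-3 SNRs clear 1.8 dB strictly", {
  snr <- rbind(c(5, 3, 2, 0, -1),     # third-largest 2.0 -> kept
               c(5, 3, 1, 0, -1),     # third-largest 1.0 -> rejected
               rep(1.8, 5))           # exactly at threshold -> rejected
  m <- qa_select(snr, selection_config())
  expect_equal(m$keep, c(TRUE, FALSE, FALSE))
  expect_equal(m$paradigm, "QA")
  # the any-of-top-3 alternative keeps the second row
  m_any <- qa_select(snr, selection_config(qa_rule = "any"))
  expect_equal(m_any$keep, c(TRUE, TRUE, FALSE))
  expect_error(qa_select(snr[, 1:2], selection_config()), "at least 3 channels")
})

test_that("QA retention is monotone in the SNR threshold", {
  set.seed(41)
  snr <- matrix(rnorm(200 * 5, mean = 2, sd = 2), 200, 5)
  kept <- sapply(c(-2, 0, 1.8, 3, 6), function(th)
    sum(qa_select(snr, selection_config(snr_threshold_db = th))$keep))
  expect_true(all(diff(kept) <= 0))
})

test_that("CR keeps windows at or above the probability threshold", {
  p <- rbind(c(0.75, rep(0.25 / 7, 7)),       # exactly at threshold -> kept
             c(0.7499, 0.2501, rep(0, 6)),    # just below -> rejected
             rep(0.125, 8),                   # uniform -> rejected
             c(0.9, 0.1, rep(0, 6)))
  m <- cr_select(p, labels = c(0, 1, 2, 3))
  expect_equal(m$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(cr_select(p[, 1:7]), "8 columns")
  expect_error(cr_select(matrix(c(-0.2, 1.2, rep(0, 6)), 1)), "malformed")
  expect_error(cr_select(matrix(rep(0.2, 8), 1)), "malformed")
})

test_that("CR retention is monotone in the confidence threshold", {
  set.seed(42)
  raw <- matrix(rexp(300 * 8), 300, 8)
  p <- raw / rowSums(raw)
  kept <- sapply(c(0, 0.3, 0.5, 0.75, 0.9, 1), function(th)
    sum(cr_select(p, cfg = selection_config(cr_threshold = th))$keep))
  expect_true(all(diff(kept) <= 0))
})

test_that("ENN matches the exhaustive brute-force oracle on random instances", {
  set.seed(43)
  for (rep_i in 1:12) {
    n <- sample(60:140, 1)
    k <- sample(3:7, 1)
    skip <- sample(0:20, 1)
    x <- matrix(rnorm(n * 6), n, 6)
    labels <- sample(0:7, n, replace = TRUE)
    cfg <- selection_config(enn_vote_k = k, enn_skip = skip)
    got <- enn_select(x, labels, cfg)$keep
    want <- oracle_enn(x, labels, skip = skip, vote_k = k)
    expect_equal(got, want)
  }
})

test_that("ENN keeps everything when labels are unanimous near each point", {
  # two tight, far-apart clusters sharing a label each: every voter agrees
  cl <- gaussian_clouds(n_per = 40, d = 3, sep = 50, classes = c(2L, 5L))
  cfg <- selection_config(enn_skip = 0L, enn_vote_k = 7L)
  expect_true(all(enn_select(cl$x, cl$labels, cfg)$keep))
  # a window whose voters all disagree is rejected
  labels2 <- cl$labels
  labels2[1] <- 7L                      # lone mislabel inside cluster of 2s
  expect_false(enn_select(cl$x, labels2, cfg)$keep[1])
})

test_that("ENN handles duplicate feature vectors (zero distances)", {
  x <- matrix(rep(c(0, 10), each = 30), ncol = 1)
  labels <- rep(c(1L, 3L), each = 30)
  cfg <- selection_config(enn_skip = 2L, enn_vote_k = 5L)
  m <- enn_select(x, labels, cfg, standardise = FALSE)
  expect_true(all(m$keep))              # duplicates vote for their own class
  expect_error(enn_select(x[1:6, , drop = FALSE], labels[1:6],
                          selection_config()), "more than")
})

test_that("selection masks are deterministic and classifier-independent", {
  set.seed(44)
  snr <- matrix(rnorm(100 * 4, 2), 100, 4)
  expect_identical(qa_select(snr)$keep, qa_select(snr)$keep)
  x <- matrix(rnorm(100 * 8), 100, 8)
  labels <- sample(0:7, 100, replace = TRUE)
  cfg <- selection_config(enn_skip = 5, enn_vote_k = 7)
  expect_identical(enn_select(x, labels, cfg)$keep,
                   enn_select(x, labels, cfg)$keep)
})

test_that("per-class retention percentages are reported", {
  snr <- rbind(c(5, 5, 5), c(0, 0, 0), c(5, 5, 5), c(5, 5, 5))
  m <- qa_select(snr, selection_config(snr_top_channels = 3L),
                 labels = c(0L, 0L, 1L, 1L))
  expect_equal(m$retention_per_class[1], 50)
  expect_equal(m$retention_per_class[2], 100)
  expect_true(all(is.na(m$retention_per_class[3:8])))
})

test_that("test rejection applies the same rules as selection", {
  cfg <- selection_config()
  snr <- rbind(c(5, 3, 2), c(5, 3, 1))
  expect_equal(reject_test("QA", list(snr_db = snr), cfg)$keep, c(TRUE, FALSE))
  p <- rbind(c(0.9, 0.1, rep(0, 6)), rep(0.125, 8))
  expect_equal(reject_test("CR", list(probabilities = p), cfg)$keep,
               c(TRUE, FALSE))
  cl <- gaussian_clouds(n_per = 40, d = 3, sep = 50)
  expect_true(all(reject_test("ENN",
                              list(features = cl$x, labels = cl$labels),
                              selection_config(enn_skip = 0))$keep))
  expect_error(reject_test("ENN", list(features = cl$x), cfg), "supervised")
  expect_true(all(reject_test("NONE", n_windows = 5)$keep))
})

test_that("masks serialise to a readable table", {
  snr <- rbind(c(5, 3, 2), c(5, 3, 1))
  m <- qa_select(snr)
  path <- tempfile(fileext = ".tsv")
  write_mask(m, path)
  tab <- read.delim(path)
  expect_equal(tab$keep, c(TRUE, FALSE))
  expect_equal(tab$paradigm, rep("QA", 2))
})
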