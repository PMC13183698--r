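test_that("error thresholds partition windows into 1 / 0 / discarded", {
  rec <- data.frame(abs_err_bpm = c(1.5, 1.99, 2.0, 4.0, 6.0, 7.0))
  lab <- label_windows(rec)
  expect_equal(lab$label, c(1L, 1L, NA, NA, NA, 0L))
  expect_equal(lab$label_reason,
               c("reliable", "reliable", "ambiguous", "ambiguous",
                 "ambiguous", "unreliable"))
  # exhaustive partition
  expect_equal(sum(lab$label == 1, na.rm = TRUE) +
                 sum(lab$label == 0, na.rm = TRUE) + sum(is.na(lab$label)),
               nrow(rec))
})

test_that("missing estimates or references get distinct discard reasons", {
  rec <- data.frame(abs_err_bpm = c(NA, NA, 1),
                    hr_ref_bpm = c(70, NA, 70))
  lab <- label_windows(rec)
  expect_equal(lab$label, c(NA, NA, 1L))
  expect_equal(lab$label_reason[1], "no_estimate")
  expect_equal(lab$label_reason[2], "no_reference")
})

test_that("every subject lands in exactly one fold, for any k and seed", {
  set.seed(20)
  for (i in 1:10) {
    n_sub <- sample(6:20, 1)
    k <- sample(2:5, 1)
    ids <- sample(paste0("s", 1:n_sub), 300, replace = TRUE)
    folds <- make_subject_folds(ids, k = k, seed = i)
    tab <- table(ids, folds)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_equal(sort(unique(folds)), seq_len(k))
  }
})

test_that("fold assignment is deterministic given the seed", {
  ids <- rep(paste0("s", 1:8), times = c(5, 9, 2, 7, 7, 3, 8, 1))
  expect_identical(make_subject_folds(ids, k = 3, seed = 99),
                   make_subject_folds(ids, k = 3, seed = 99))
})

test_that("equal per-subject counts balance folds exactly", {
  ids <- rep(paste0("s", 1:5), each = 100)
  folds <- make_subject_folds(ids, k = 5, seed = 1)
  expect_equal(unname(table(folds)), rep(100L, 5), ignore_attr = TRUE)
})

test_that("greedy balancing matches the exhaustive optimum for k = 2", {
  counts <- c(s1 = 90, s2 = 80, s3 = 70, s4 = 30, s5 = 30)
  ids <- rep(names(counts), times = counts)
  folds <- make_subject_folds(ids, k = 2, seed = 3)
  greedy_max <- max(table(folds))
  # brute force over all 2^5 assignments with both folds nonempty
  best <- Inf
  for (m in 0:31) {
    a <- as.logical(bitwAnd(m, 2^(0:4)))
    if (all(a) || !any(a)) next
    best <- min(best, max(sum(counts[a]), sum(counts[!a])))
  }
  expect_equal(greedy_max, best)
})

test_that("fewer subjects than folds is an error", {
  expect_error(make_subject_folds(rep(c("a", "b"), 10), k = 5),
               "at least k")
})
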