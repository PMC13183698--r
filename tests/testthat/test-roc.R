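test_that("ROC/AUC handles perfect separation, ties and mixed ranks", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 8), rep(c(1, 0), 4))$auc, 0.5)
  expect_equal(roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both")
})

test_that("AUC equals the brute-force pairwise oracle on random instances", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # force some ties
    expect_equal(roc_curve(scores, labels)$auc, brute_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(31)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  a0 <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(exp(scores), labels)$auc, a0)
  expect_equal(roc_curve(qnorm(pnorm(scores))^3 + 10, labels)$auc, a0)
})

test_that("the ROC curve is monotone and integrates to the rank AUC", {
  set.seed(32)
  scores <- round(runif(80), 2)
  labels <- rbinom(80, 1, 0.5)
  roc <- roc_curve(scores, labels)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  # trapezoidal integral of the full curve (append (1,1))
  fpr <- c(roc$points$fpr, 1); tpr <- c(roc$points$tpr, 1)
  trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  expect_equal(trap, roc$auc, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- runif(100)
  labels <- rbinom(100, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<",
                                               levels = c(0, 1))))
  expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("Pearson correlation matches definition and cor.test", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  expect_equal(pearson_correlation(1:10, -2 * (1:10) + 3)$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pc <- pearson_correlation(x, y)
  expect_equal(pc$r, r_hand)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p_value, ct$p.value)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})
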