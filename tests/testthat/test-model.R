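test_that("a separable table gives training AUC 1 and ordered centroid scores", {
  tab <- generate_feature_table(300, separation = 6, seed = 1)
  m <- confidence_model(tab, seed = 1)
  sc <- predict(m, tab)
  expect_equal(roc_curve(sc, tab$label)$auc, 1)
  # class centroids: class 1 at origin, class 0 shifted on TI
  c1 <- data.frame(TI = 0, FM_X = 0, FM_Y = 0, FSM = 0)
  c0 <- data.frame(TI = 6, FM_X = 0, FM_Y = 0, FSM = 0)
  expect_gt(predict(m, c1), 0.9)
  expect_lt(predict(m, c0), 0.1)
})

test_that("model fitting and scoring are deterministic given the seed", {
  tab <- generate_feature_table(150, separation = 1.5, seed = 4)
  s1 <- predict(confidence_model(tab, seed = 7), tab)
  s2 <- predict(confidence_model(tab, seed = 7), tab)
  expect_identical(s1, s2)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  tab <- generate_feature_table(1000, separation = 2, seed = 2)
  set.seed(99)
  tab$label <- sample(tab$label)
  cv <- cross_validate_scores(tab, k = 5, seed = 1)
  auc <- roc_curve(cv$score, cv$label)$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("single-class training data and non-finite features are rejected", {
  tab <- generate_feature_table(50, separation = 1, seed = 3)
  tab1 <- tab[tab$label == 1, ]
  expect_error(confidence_model(tab1, seed = 1), "both")
  m <- confidence_model(tab, seed = 1)
  bad <- data.frame(TI = NA_real_, FM_X = 0, FM_Y = 0, FSM = 0)
  expect_error(predict(m, bad), "non-finite")
})

test_that("every classifier in the roster fits, scores in [0,1], separates", {
  tab <- generate_feature_table(120, separation = 5, seed = 6)
  roster <- c("bagged_trees", "boosted_trees", "tree", "lda", "logistic",
              "naive_bayes", "svm_linear", "svm_rbf", "knn1", "mlp")
  for (cl in roster) {
    # logistic regression warns about perfect separation on this fixture
    m <- suppressWarnings(confidence_model(tab, classifier = cl, seed = 2))
    sc <- predict(m, tab)
    expect_true(all(sc >= 0 & sc <= 1), info = cl)
    expect_gt(roc_curve(sc, tab$label)$auc, 0.95)
  }
})

test_that("print and summary report the configuration", {
  tab <- generate_feature_table(50, separation = 2, seed = 8)
  m <- confidence_model(tab, seed = 1)
  expect_output(print(m), "bagged_trees")
  expect_output(summary(m), "n_trees=30")
})
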