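# A small synthetic record set with three pseudo-datasets whose labels are
# driven by the features, for exercising the evaluation harness quickly.
make_eval_records <- function(n_per_sub = 40, seed = 1) {
  set.seed(seed)
  out <- list()
  for (d in c("dsA", "dsB", "dsC")) {
    for (s in 1:5) {
      sub <- paste0(d, "_s", s)
      sev <- runif(n_per_sub, 0, 4)
      feats <- matrix(rnorm(n_per_sub * 4, mean = sev, sd = 0.6),
                      n_per_sub, 4)
      colnames(feats) <- c("TI", "FM_X", "FM_Y", "FSM")
      rec <- data.frame(feats)
      rec$subject_id <- sub
      rec$dataset_id <- d
      rec$method <- "GREEN"
      rec$abs_err_bpm <- ifelse(sev > 2, 8, 1) + rnorm(n_per_sub, sd = 0.3)
      out[[length(out) + 1]] <- rec
    }
  }
  label_windows(do.call(rbind, out))
}

test_that("cross-validated scoring keeps train and test subjects disjoint", {
  rec <- make_eval_records()
  cv <- cross_validate_scores(rec, k = 5, seed = 2)
  tab <- table(cv$subject_id, cv$fold)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(!is.na(cv$score[!is.na(cv$label)])))
})

test_that("all three evaluation schemes run with subject discipline", {
  rec <- make_eval_records()
  for (scheme in c("within_dataset", "combined", "cross_dataset")) {
    ev <- evaluate_confidence(rec, scheme = scheme, seed = 1)
    expect_s3_class(ev, "rppg_evaluation")
    expect_true(all(ev$auc$auc >= 0 & ev$auc$auc <= 1))
    # label tallies partition the records
    expect_equal(sum(ev$tally$Freq), nrow(rec))
  }
  ev <- evaluate_confidence(rec, scheme = "within_dataset", seed = 1)
  expect_equal(nrow(ev$auc), 3)  # one row per dataset for the one method
})

test_that("cross-dataset evaluation requires several datasets", {
  rec <- make_eval_records()
  rec1 <- rec[rec$dataset_id == "dsA", ]
  expect_error(evaluate_confidence(rec1, scheme = "cross_dataset"),
               "at least 2")
})

test_that("feature-error correlations are positive on severity-driven data", {
  rec <- make_eval_records()
  fc <- feature_error_correlation(rec)
  expect_equal(fc$feature, c("TI", "FM_X", "FM_Y", "FSM"))
  expect_true(all(fc$r > 0))
  expect_true(all(fc$p_value < 1e-6))
})

test_that("the synthetic feature table is deterministic and well-formed", {
  t1 <- generate_feature_table(3, separation = 1, seed = 5)
  t2 <- generate_feature_table(3, separation = 1, seed = 5)
  expect_identical(t1, t2)
  expect_equal(table(t1$label), table(c(0, 0, 0, 1, 1, 1)), ignore_attr = TRUE)
})

test_that("a zero-separation table yields chance AUC for a simple classifier", {
  tab <- generate_feature_table(800, separation = 0, seed = 9)
  cv <- cross_validate_scores(tab, classifier = "logistic", k = 5, seed = 1)
  expect_lt(abs(roc_curve(cv$score, cv$label)$auc - 0.5), 0.05)
})
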