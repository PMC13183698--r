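#' Cross-validated confidence scores with subject discipline
#'
#' Runs k-fold cross-validation of a [confidence_model()] with
#' subject-stratified folds: each fold's scores come from a model trained on
#' the other folds, so no subject's windows appear on both sides. Discarded
#' (`label = NA`) records receive no score.
#'
#' @param data Labeled window records (see [label_windows()]) with a
#'   `subject_id` column.
#' @param classifier Classifier name (see [confidence_model()]).
#' @param k Number of folds.
#' @param seed Integer seed for folds and model fitting.
#' @param ... Passed to [confidence_model()].
#' @return `data` with added columns `fold` and `score`.
#' @export
cross_validate_scores <- function(data, classifier = "bagged_trees", k = 5,
                                  seed = 1L, ...) {
  data$fold <- make_subject_folds(data$subject_id, k = k, seed = seed)
  data$score <- NA_real_
  usable <- !is.na(data$label)
  for (f in sort(unique(data$fold))) {
    tr <- usable & data$fold != f
    te <- usable & data$fold == f
    if (!any(te)) next
    m <- confidence_model(data[tr, ], classifier = classifier,
                          seed = seed + f, ...)
    data$score[te] <- predict(m, data[te, ])
  }
  data
}

#' Evaluate the confidence score under a cross-validation scheme
#'
#' Runs one of the three evaluation harnesses on labeled window records,
#' always keeping train and test subject sets disjoint:
#' \describe{
#'   \item{`within_dataset`}{subject-stratified k-fold CV inside each
#'     dataset separately.}
#'   \item{`combined`}{subject-stratified k-fold CV over all datasets
#'     pooled.}
#'   \item{`cross_dataset`}{for each dataset, train on all other datasets
#'     and test on it.}
#' }
#' Records are evaluated per BVP method when a `method` column is present.
#'
#' @param records Labeled window records with `subject_id`, `dataset_id`,
#'   optionally `method`, the four features and `label`.
#' @param classifier Classifier name.
#' @param scheme Evaluation scheme (see Details).
#' @param k Folds for the CV-based schemes.
#' @param seed Integer seed.
#' @param ... Passed to [confidence_model()].
#' @return Object of class `rppg_evaluation`: list with `auc` (data frame
#'   `scheme`, `method`, `unit`, `auc`, `n_pos`, `n_neg`), `tally` (label
#'   counts per dataset and method), `scheme`, `classifier`.
#' @export
evaluate_confidence <- function(records,
                                classifier = "bagged_trees",
                                scheme = c("within_dataset", "combined",
                                           "cross_dataset"),
                                k = 5, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  if (is.null(records$method)) records$method <- "ALL"
  if (is.null(records$dataset_id)) records$dataset_id <- "all"
  datasets <- unique(records$dataset_id)
  if (scheme == "cross_dataset" && length(datasets) < 2) {
    stop("cross_dataset evaluation needs at least 2 datasets")
  }
  rows <- list()
  for (m in unique(records$method)) {
    rm <- records[records$method == m, ]
    if (scheme == "within_dataset") {
      for (d in datasets) {
        rd <- rm[rm$dataset_id == d, ]
        sc <- cross_validate_scores(rd, classifier, k, seed, ...)
        rows[[length(rows) + 1]] <- auc_row(sc, scheme, m, d)
      }
    } else if (scheme == "combined") {
      sc <- cross_validate_scores(rm, classifier, k, seed, ...)
      rows[[length(rows) + 1]] <- auc_row(sc, scheme, m, "combined")
    } else {
      for (d in datasets) {
        tr <- rm[rm$dataset_id != d & !is.na(rm$label), ]
        te <- rm[rm$dataset_id == d & !is.na(rm$label), ]
        if (length(intersect(tr$subject_id, te$subject_id)) > 0) {
          stop("subjects shared across datasets: cross-dataset scheme unsafe")
        }
        mod <- confidence_model(tr, classifier = classifier, seed = seed, ...)
        te$score <- predict(mod, te)
        rows[[length(rows) + 1]] <- auc_row(te, scheme, m, d)
      }
    }
  }
  tally <- label_tally(records)
  structure(list(auc = do.call(rbind, rows), tally = tally,
                 scheme = scheme, classifier = classifier),
            class = "rppg_evaluation")
}

auc_row <- function(scored, scheme, method, unit) {
  ok <- !is.na(scored$label) & !is.na(scored$score)
  roc <- roc_curve(scored$score[ok], scored$label[ok])
  data.frame(scheme = scheme, method = method, unit = unit,
             auc = roc$auc, n_pos = roc$n_pos, n_neg = roc$n_neg,
             stringsAsFactors = FALSE)
}

# Reliable / unreliable / discarded counts per dataset and method.
label_tally <- function(records) {
  status <- ifelse(is.na(records$label), "discarded",
                   ifelse(records$label == 1, "reliable", "unreliable"))
  as.data.frame(table(dataset_id = records$dataset_id,
                      method = records$method, status = status),
                stringsAsFactors = FALSE)
}

#' @export
print.rppg_evaluation <- function(x, ...) {
  cat("Confidence-score evaluation (", x$scheme, ", ", x$classifier, ")\n",
      sep = "")
  print(x$auc, row.names = FALSE)
  invisible(x)
}

#' Correlation between each motion feature and the absolute HR error
#'
#' For each of the four motion features, the Pearson correlation (and
#' t-test p-value) between the feature and the absolute heart-rate error
#' over all windows with an estimate — the feature-relevance analysis
#' behind the confidence model.
#'
#' @param records Window records with the feature columns and
#'   `abs_err_bpm`.
#' @return Data frame `feature`, `r`, `p_value`, `n`.
#' @export
feature_error_correlation <- function(records) {
  ok <- is.finite(records$abs_err_bpm)
  do.call(rbind, lapply(CONF_FEATURES, function(f) {
    pc <- pearson_correlation(records[[f]][ok], records$abs_err_bpm[ok])
    data.frame(feature = f, r = pc$r, p_value = pc$p_value, n = pc$n,
               stringsAsFactors = FALSE)
  }))
}
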