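CONF_FEATURES <- c("TI", "FM_X", "FM_Y", "FSM")

#' Fit a motion-based confidence model for rPPG heart-rate estimates
#'
#' Trains a classifier that predicts, from the four per-window motion
#' features (TI, FM_X, FM_Y, FSM), whether a heart-rate measurement is
#' reliable, and emits a continuous confidence score in [0, 1] rather than a
#' hard label. Records with `label = NA` (ambiguous error band, missing
#' estimate or reference) are excluded from training.
#'
#' The default classifier is a bagged-trees ensemble: 30 bootstrap decision
#' trees, each cost-complexity-pruned to at most 9 splits, scored by the
#' mean of the per-tree class-1 terminal-node probabilities. The full roster
#' of alternatives mirrors the usual tabular-classifier lineup:
#' \describe{
#'   \item{`bagged_trees`}{30 trees, <= 9 splits each (default).}
#'   \item{`boosted_trees`}{discrete AdaBoost, 30 learners, learning rate
#'     0.1, shallow trees (depth 4).}
#'   \item{`tree`}{single decision tree, Gini splits, <= 100 splits.}
#'   \item{`lda`}{linear discriminant analysis.}
#'   \item{`logistic`}{logistic regression.}
#'   \item{`naive_bayes`}{Gaussian naive Bayes.}
#'   \item{`svm_linear`, `svm_rbf`}{support vector machines with Platt
#'     probability outputs.}
#'   \item{`knn1`}{1-nearest-neighbour (score is the neighbour's label).}
#'   \item{`mlp`}{single-hidden-layer neural network, 10 units.}
#' }
#'
#' @param data Data frame containing the feature columns `TI`, `FM_X`,
#'   `FM_Y`, `FSM` and a `label` column with values 1 (reliable), 0
#'   (unreliable) or `NA` (discarded); see [label_windows()].
#' @param classifier Classifier name (see Details).
#' @param seed Integer seed for bootstrap/initialisation randomness.
#' @param ... Classifier-specific overrides: `n_trees`, `max_splits`,
#'   `learn_rate`, `hidden` as applicable.
#' @return An object of class `confidence_model` with elements `fit`,
#'   `classifier`, `features`, `n_train`, `class_counts`, `seed`, `config`.
#' @seealso [predict.confidence_model()], [roc_curve()], [evaluate_confidence()]
#' @examples
#' tab <- generate_feature_table(200, separation = 2, seed = 1)
#' m <- confidence_model(tab)
#' summary(m)
#' @export
confidence_model <- function(data, classifier = "bagged_trees", seed = 1L,
                             ...) {
  classifier <- match.arg(classifier, names(classifier_registry()))
  stopifnot(all(CONF_FEATURES %in% names(data)), "label" %in% names(data))
  keep <- !is.na(data$label)
  x <- as.matrix(data[keep, CONF_FEATURES])
  y <- factor(data$label[keep], levels = c(0, 1))
  if (any(!is.finite(x))) stop("non-finite feature values in training data")
  if (nlevels(droplevels(y)) < 2) {
    stop("training data must contain both reliable and unreliable windows")
  }
  cfg <- utils::modifyList(classifier_registry()[[classifier]]$defaults,
                           list(...))
  fit <- with_seed(seed,
                   classifier_registry()[[classifier]]$fit(x, y, cfg))
  structure(list(fit = fit, classifier = classifier,
                 features = CONF_FEATURES, n_train = nrow(x),
                 class_counts = table(y), seed = as.integer(seed),
                 config = cfg),
            class = "confidence_model")
}

#' Predict confidence scores
#'
#' @param object A fitted [confidence_model()].
#' @param newdata Data frame with columns `TI`, `FM_X`, `FM_Y`, `FSM`.
#' @param ... Unused.
#' @return Numeric vector of confidence scores in [0, 1]; higher means more
#'   likely reliable.
#' @export
predict.confidence_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values")
  s <- classifier_registry()[[object$classifier]]$score(object$fit, x)
  pmin(pmax(as.numeric(s), 0), 1)
}

#' @export
print.confidence_model <- function(x, ...) {
  cat("Motion-based rPPG confidence model\n")
  cat("  classifier:", x$classifier, "\n")
  cat("  features:  ", paste(x$features, collapse = ", "), "\n")
  cat("  training:  ", x$n_train, "windows (",
      x$class_counts[["1"]], "reliable /", x$class_counts[["0"]],
      "unreliable )\n")
  invisible(x)
}

#' @export
summary.confidence_model <- function(object, ...) {
  print(object)
  cfg <- object$config
  if (length(cfg)) {
    cat("  config:    ",
        paste(names(cfg), unlist(cfg), sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
plot.confidence_model <- function(x, data, ...) {
  stopifnot(!missing(data))
  keep <- !is.na(data$label)
  roc <- roc_curve(predict(x, data[keep, ]), data$label[keep])
  plot(roc, ...)
  invisible(roc)
}

## ---- classifier registry ------------------------------------------------

classifier_registry <- function() {
  list(
    bagged_trees = list(
      defaults = list(n_trees = 30, max_splits = 9),
      fit = fit_bagged_trees, score = score_bagged_trees),
    boosted_trees = list(
      defaults = list(n_trees = 30, max_splits = 20, learn_rate = 0.1),
      fit = fit_boosted_trees, score = score_boosted_trees),
    tree = list(
      defaults = list(max_splits = 100),
      fit = fit_single_tree, score = score_rpart),
    lda = list(
      defaults = list(),
      fit = function(x, y, cfg) MASS::lda(x, grouping = y),
      score = function(fit, x) stats::predict(fit, x)$posterior[, "1"]),
    logistic = list(
      defaults = list(),
      fit = function(x, y, cfg) {
        stats::glm(y ~ ., data = data.frame(x, y = y),
                   family = stats::binomial())
      },
      score = function(fit, x) {
        stats::predict(fit, data.frame(x), type = "response")
      }),
    naive_bayes = list(
      defaults = list(),
      fit = function(x, y, cfg) e1071::naiveBayes(x, y),
      score = function(fit, x) {
        stats::predict(fit, x, type = "raw")[, "1"]
      }),
    svm_linear = list(
      defaults = list(),
      fit = function(x, y, cfg) {
        e1071::svm(x, y, kernel = "linear", probability = TRUE)
      },
      score = score_svm),
    svm_rbf = list(
      defaults = list(),
      fit = function(x, y, cfg) {
        e1071::svm(x, y, kernel = "radial", probability = TRUE)
      },
      score = score_svm),
    knn1 = list(
      defaults = list(),
      fit = function(x, y, cfg) list(x = x, y = y),
      score = function(fit, x) {
        as.numeric(as.character(class::knn(fit$x, x, fit$y, k = 1)))
      }),
    mlp = list(
      defaults = list(hidden = 10),
      fit = function(x, y, cfg) {
        nnet::nnet(x, as.numeric(as.character(y)), size = cfg$hidden,
                   decay = 1e-4, maxit = 300, trace = FALSE)
      },
      score = function(fit, x) as.numeric(stats::predict(fit, x)))
  )
}

score_svm <- function(fit, x) {
  attr(stats::predict(fit, x, probability = TRUE), "probabilities")[, "1"]
}

# Grow a tree on (possibly weighted) data and cost-complexity prune it back
# to at most `max_splits` splits — the per-tree cap of the ensemble configs.
grow_pruned_tree <- function(df, max_splits, weights = NULL) {
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                               maxdepth = 30, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      weights = weights, control = ctrl)
  ct <- fit$cptable
  ok <- ct[ct[, "nsplit"] <= max_splits, , drop = FALSE]
  rpart::prune(fit, cp = ok[nrow(ok), "CP"] + 1e-12)
}

fit_bagged_trees <- function(x, y, cfg) {
  n <- nrow(x)
  df <- data.frame(x, .y = y)
  trees <- lapply(seq_len(cfg$n_trees), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_pruned_tree(df[idx, , drop = FALSE], cfg$max_splits)
  })
  list(trees = trees)
}

score_bagged_trees <- function(fit, x) {
  df <- data.frame(x)
  p <- vapply(fit$trees,
              function(t) stats::predict(t, df, type = "prob")[, "1"],
              numeric(nrow(df)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  rowMeans(p)
}

# Discrete AdaBoost over shallow trees. Depth-4 trees keep each learner
# under the 20-split cap; alpha steps are shrunk by the learning rate.
fit_boosted_trees <- function(x, y, cfg) {
  n <- nrow(x)
  df <- data.frame(x, .y = y)
  w <- rep(1 / n, n)
  yy <- ifelse(y == "1", 1, -1)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(cfg$n_trees)) {
    ctrl <- rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                                 maxdepth = 4, xval = 0, maxcompete = 0,
                                 maxsurrogate = 0, usesurrogate = 0)
    t <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                      control = ctrl)
    pred <- ifelse(stats::predict(t, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err <= 0) {
      learners[[m]] <- t; alphas[m] <- 5  # perfect learner dominates
      break
    }
    if (err >= 0.5) break
    a <- cfg$learn_rate * 0.5 * log((1 - err) / err)
    learners[[m]] <- t
    alphas[m] <- a
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (length(learners) == 0) {  # no learner beat chance: constant score
    learners <- list(NULL); alphas <- 0
  }
  list(learners = learners, alphas = alphas)
}

score_boosted_trees <- function(fit, x) {
  df <- data.frame(x)
  if (length(fit$learners) == 1 && is.null(fit$learners[[1]])) {
    return(rep(0.5, nrow(df)))
  }
  votes <- vapply(fit$learners, function(t) {
    ifelse(stats::predict(t, df, type = "class") == "1", 1, 0)
  }, numeric(nrow(df)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  as.numeric(votes %*% fit$alphas) / sum(fit$alphas)
}

fit_single_tree <- function(x, y, cfg) {
  grow_pruned_tree(data.frame(x, .y = y), cfg$max_splits)
}

score_rpart <- function(fit, x) {
  stats::predict(fit, data.frame(x), type = "prob")[, "1"]
}
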