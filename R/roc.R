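#' ROC curve and AUC for confidence scores
#'
#' Builds the receiver operating characteristic curve over all score
#' thresholds and computes the area under it via the rank (probability)
#' definition: the probability that a randomly chosen reliable window scores
#' higher than a randomly chosen unreliable one, with ties counted as 1/2.
#' This equals the trapezoidal integral of the ROC curve.
#'
#' @param scores Numeric confidence scores.
#' @param labels Binary labels (1 reliable / 0 unreliable); `NA` labels are
#'   dropped.
#' @return Object of class `rppg_roc`: list with `points` (data frame of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_curve <- function(scores, labels) {
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]
  labels <- as.integer(as.character(labels[keep]))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both reliable and unreliable windows")
  }
  r <- rank(scores)  # midranks: ties contribute 1/2
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0) / n_neg,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "rppg_roc")
}

#' @export
print.rppg_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d reliable, %d unreliable)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.rppg_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Pearson correlation with t-test p-value
#'
#' Computes the Pearson correlation coefficient as the ratio of the
#' covariance of two variables to the product of their standard deviations,
#' together with the p-value of the usual t approximation — used to relate
#' each motion feature to the absolute heart-rate error.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("correlation undefined for zero variance")
  r <- stats::cov(x, y) / (sx * sy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p_value = p, n = n)
}
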