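#' Synthetic labeled feature table with known Bayes AUC
#'
#' Draws balanced 4-dimensional Gaussian feature vectors for two classes
#' with unit spherical covariance. Class 1 (reliable) is centered at the
#' origin; class 0 (unreliable) is shifted by `separation` along the first
#' feature axis. For equal spherical covariances the optimal (Bayes) AUC has
#' the closed form \eqn{\Phi(d/\sqrt{2})}, which makes the table a
#' calibration fixture for any classifier: e.g. d = 2 gives
#' \eqn{\Phi(\sqrt{2}) \approx 0.921}, and d = 0 gives 0.5.
#'
#' @param n_per_class Samples per class.
#' @param separation Mean shift d >= 0 between the classes.
#' @param seed Integer seed.
#' @return Data frame with columns `TI`, `FM_X`, `FM_Y`, `FSM`, `label`
#'   (1 then 0), `subject_id` (round-robin pseudo-subjects so the table can
#'   feed subject-stratified folds).
#' @export
generate_feature_table <- function(n_per_class, separation, seed = 1L) {
  stopifnot(n_per_class >= 1, separation >= 0)
  with_seed(seed, {
    x1 <- matrix(stats::rnorm(n_per_class * 4), n_per_class, 4)
    x0 <- matrix(stats::rnorm(n_per_class * 4), n_per_class, 4)
    x0[, 1] <- x0[, 1] + separation
    x <- rbind(x1, x0)
  })
  colnames(x) <- CONF_FEATURES
  out <- data.frame(x)
  out$label <- rep(c(1L, 0L), each = n_per_class)
  out$subject_id <- paste0("s", (seq_len(2 * n_per_class) %% 20) + 1)
  out
}
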