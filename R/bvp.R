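#' Blood volume pulse extraction from an ROI color trace
#'
#' Turns a per-frame ROI-mean RGB trace into a 1-D blood volume pulse (BVP)
#' signal using one of three standard methods:
#' \describe{
#'   \item{GREEN}{the mean-subtracted green channel — the classical baseline,
#'     sensitive to any intensity distortion.}
#'   \item{CHROM}{chrominance projection: channels are normalized by their
#'     window means (\eqn{C_n = C/\bar{C}}), then
#'     \eqn{X = 3R_n - 2G_n}, \eqn{Y = 1.5R_n + G_n - 1.5B_n} and
#'     \eqn{S = X - (\sigma_X/\sigma_Y) Y}; S is mean-subtracted.}
#'   \item{POS}{plane-orthogonal-to-skin projection: temporally
#'     mean-normalized channels, \eqn{S_1 = G_n - B_n},
#'     \eqn{S_2 = G_n + B_n - 2R_n},
#'     \eqn{h = S_1 + (\sigma_{S_1}/\sigma_{S_2}) S_2}, mean-subtracted.}
#' }
#' CHROM and POS project out the global intensity direction, so they are
#' invariant to multiplicative intensity distortions that corrupt GREEN.
#' The projection is applied over the full analysis window.
#'
#' @param trace An n x 3 numeric matrix (columns R, G, B) of ROI channel
#'   means, n >= 2, or a data frame with columns R, G, B.
#' @param method One of `"GREEN"`, `"CHROM"`, `"POS"`.
#' @return Numeric BVP signal of length n with zero mean, with attributes
#'   `method`.
#' @examples
#' t <- seq(0, 12, by = 1 / 30)
#' tr <- cbind(R = 120 + 0.3 * sin(2 * pi * 1.2 * t),
#'             G = 140 + 1.0 * sin(2 * pi * 1.2 * t),
#'             B = 110 + 0.5 * sin(2 * pi * 1.2 * t))
#' bvp <- extract_bvp(tr, "POS")
#' @export
extract_bvp <- function(trace, method = c("GREEN", "CHROM", "POS")) {
  method <- match.arg(method)
  trace <- as.matrix(trace)
  if (ncol(trace) != 3) stop("trace must have 3 columns (R, G, B)")
  if (nrow(trace) < 2) stop("trace must have at least 2 samples")
  s <- switch(method,
              GREEN = trace[, 2],
              CHROM = chrom_projection(trace),
              POS = pos_projection(trace))
  s <- s - mean(s)
  attr(s, "method") <- method
  s
}

chrom_projection <- function(trace) {
  mu <- colMeans(trace)
  if (any(mu <= 0)) stop("CHROM requires positive channel means")
  rn <- trace[, 1] / mu[1]; gn <- trace[, 2] / mu[2]; bn <- trace[, 3] / mu[3]
  x <- 3 * rn - 2 * gn
  y <- 1.5 * rn + gn - 1.5 * bn
  sy <- stats::sd(y)
  if (sy == 0) return(x)  # degenerate: no chrominance variation in Y
  x - (stats::sd(x) / sy) * y
}

pos_projection <- function(trace) {
  mu <- colMeans(trace)
  if (any(mu <= 0)) stop("POS requires positive channel means")
  rn <- trace[, 1] / mu[1]; gn <- trace[, 2] / mu[2]; bn <- trace[, 3] / mu[3]
  s1 <- gn - bn
  s2 <- gn + bn - 2 * rn
  sd2 <- stats::sd(s2)
  if (sd2 == 0) return(s1)
  s1 + (stats::sd(s1) / sd2) * s2
}

#' Band-pass filter and window a BVP signal
#'
#' Applies a zero-phase Butterworth band-pass filter (forward-backward via
#' `signal::filtfilt`) restricted to the physiological pulse band, then
#' multiplies the result by a Hann window of the signal length, preparing the
#' signal for spectral peak estimation.
#'
#' @param x Numeric BVP signal.
#' @param fps Sampling rate in frames/s.
#' @param band Passband in Hz (default 0.65--4.0 Hz, i.e. 39--240 bpm).
#' @param order Butterworth filter order (default 6).
#' @return Filtered, Hann-windowed signal of the same length.
#' @export
bandpass_filter <- function(x, fps, band = c(0.65, 4), order = 6) {
  stopifnot(fps > 0, length(band) == 2, band[1] > 0, band[2] > band[1])
  if (band[2] >= fps / 2) {
    stop("passband upper edge must be below the Nyquist frequency fps/2")
  }
  n <- length(x)
  if (n < 3 * order) stop("signal too short for the filter order")
  bf <- signal::butter(order, band / (fps / 2), type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  y * hann_window(n)
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}
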