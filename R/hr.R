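#' Spectral heart-rate estimate from a BVP signal
#'
#' Computes the power spectral density of a filtered, windowed BVP signal by
#' zero-padded periodogram (padding to at least 8192 points), finds the
#' maximum-power bin inside the pulse band, refines its frequency by
#' three-point parabolic interpolation on the power values around the peak,
#' and converts to beats per minute.
#'
#' @param x Filtered, Hann-windowed BVP signal (see [bandpass_filter()]).
#' @param fps Sampling rate in frames/s.
#' @param band Search band in Hz (default 0.65--4.0).
#' @param nfft Minimum FFT length (zero-padded; default 8192).
#' @return Heart rate in bpm, or `NA_real_` when the in-band spectrum is
#'   identically zero (no estimate possible).
#' @examples
#' fps <- 30; t <- seq(0, 12, by = 1 / fps)[1:(12 * fps)]
#' x <- bandpass_filter(sin(2 * pi * 1.2 * t), fps)
#' estimate_hr(x, fps)  # ~72 bpm
#' @export
estimate_hr <- function(x, fps, band = c(0.65, 4), nfft = 8192) {
  n <- length(x)
  stopifnot(n >= 2, fps > 0)
  m <- max(nfft, 2^ceiling(log2(n)))
  p <- abs(stats::fft(c(x, rep(0, m - n))))^2
  freq <- (seq_len(m) - 1) * fps / m
  idx <- which(freq >= band[1] & freq <= band[2])
  if (length(idx) == 0 || all(p[idx] == 0)) return(NA_real_)
  k <- idx[which.max(p[idx])]
  # parabolic refinement on the three bins around the peak
  delta <- 0
  if (k > 1 && k < m) {
    a <- p[k - 1]; b <- p[k]; c <- p[k + 1]
    den <- a - 2 * b + c
    if (den < 0) delta <- 0.5 * (a - c) / den
    if (abs(delta) > 0.5) delta <- 0
  }
  60 * (k - 1 + delta) * fps / m
}

#' Sliding analysis windows over a video
#'
#' One window per whole second `t >= window_s`, covering the immediately
#' preceding `window_s` seconds `(t - window_s, t]`, advanced by `hop_s`.
#' Frame indices are 1-based.
#'
#' @param n_frames Number of frames in the video.
#' @param fps Frame rate in frames/s.
#' @param window_s Window length in seconds (default 12).
#' @param hop_s Hop between windows in seconds (default 1).
#' @return Data frame with columns `window_end_s`, `start_frame`,
#'   `end_frame`; zero rows when the video is shorter than `window_s`.
#' @examples
#' nrow(sliding_windows(68 * 30, 30))  # 57
#' @export
sliding_windows <- function(n_frames, fps, window_s = 12, hop_s = 1) {
  stopifnot(fps > 0, window_s > 0, hop_s > 0, window_s > hop_s)
  dur <- n_frames / fps
  if (dur < window_s) {
    return(data.frame(window_end_s = numeric(0), start_frame = integer(0),
                      end_frame = integer(0)))
  }
  ends <- seq(window_s, floor(dur / hop_s) * hop_s, by = hop_s)
  ends <- ends[ends <= dur + 1e-9]
  wf <- round(window_s * fps)
  end_frame <- pmin(round(ends * fps), n_frames)
  data.frame(window_end_s = ends,
             start_frame = as.integer(end_frame - wf + 1L),
             end_frame = as.integer(end_frame))
}

#' Ground-truth heart rate for one window
#'
#' Averages the instantaneous heart-rate channel of a reference trace over
#' the window `(t_end - window_s, t_end]`. When the trace carries no
#' `hr_bpm` column, the heart rate is estimated from the reference waveform
#' itself with the same spectral estimator used for the video signal.
#'
#' @param reference A data frame with columns `time_s`, `ppg` and
#'   optionally `hr_bpm` (see [generate_pulse_waveform()]).
#' @param t_end Window end time in seconds.
#' @param window_s Window length in seconds (default 12).
#' @return Reference heart rate in bpm.
#' @export
reference_hr <- function(reference, t_end, window_s = 12) {
  sel <- reference$time_s > t_end - window_s - 1e-9 &
    reference$time_s <= t_end + 1e-9
  if (!any(sel)) stop("reference trace does not overlap the window")
  if (!is.null(reference$hr_bpm)) {
    return(mean(reference$hr_bpm[sel]))
  }
  ts <- reference$time_s[sel]
  fs <- 1 / stats::median(diff(ts))
  estimate_hr(bandpass_filter(reference$ppg[sel], fs), fs)
}
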