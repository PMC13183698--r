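#' Generate a synthetic pulse waveform with known instantaneous heart rate
#'
#' Produces an oximeter-style reference trace: a (optionally two-harmonic)
#' sinusoidal pulse waveform whose instantaneous frequency follows a
#' prescribed heart-rate trajectory, sampled at `sample_rate`. The trace
#' carries both the waveform and the instantaneous heart rate, mirroring the
#' finger-clip pulse oximeter recordings (typically 60 Hz) used as ground
#' truth in rPPG studies.
#'
#' The waveform is \eqn{s(t) = \sin(2\pi \int_0^t f(\tau)\,d\tau) +
#' a_2 \sin(4\pi \int_0^t f(\tau)\,d\tau)} with \eqn{f} in Hz (bpm / 60).
#' A second harmonic at relative amplitude `harmonic2` gives the trace a
#' mildly PPG-like asymmetry; it does not move the spectral peak.
#'
#' @param hr_trajectory Either a single number (constant heart rate in bpm)
#'   or a function of time in seconds returning bpm. Must stay within
#'   40--240 bpm over the requested duration.
#' @param duration Length of the trace in seconds.
#' @param sample_rate Sampling rate in Hz (default 60, the usual oximeter
#'   rate). Must exceed twice the maximum pulse frequency.
#' @param harmonic2 Relative amplitude of the second harmonic (default 0.3).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   waveform (default 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#'
#' @return A data frame of class `reference_trace` with columns `time_s`,
#'   `ppg` and `hr_bpm`.
#' @examples
#' ref <- generate_pulse_waveform(72, duration = 10)
#' range(ref$hr_bpm)
#' @export
generate_pulse_waveform <- function(hr_trajectory, duration, sample_rate = 60,
                                    harmonic2 = 0.3, noise_sd = 0, seed = 1L) {
  stopifnot(duration > 0, sample_rate > 0)
  f_bpm <- as_hr_function(hr_trajectory)
  t <- seq(0, duration, by = 1 / sample_rate)
  hr <- f_bpm(t)
  if (any(!is.finite(hr)) || any(hr < 40) || any(hr > 240)) {
    stop("heart-rate trajectory must stay within [40, 240] bpm")
  }
  if (sample_rate < 2 * max(hr) / 60) {
    stop("sample_rate must be at least twice the maximum pulse frequency")
  }
  phase <- 2 * pi * cumsum(hr / 60) / sample_rate
  ppg <- sin(phase) + harmonic2 * sin(2 * phase)
  if (noise_sd > 0) {
    ppg <- ppg + with_seed(seed, stats::rnorm(length(ppg), sd = noise_sd))
  }
  out <- data.frame(time_s = t, ppg = ppg, hr_bpm = hr)
  class(out) <- c("reference_trace", "data.frame")
  out
}

#' @keywords internal
as_hr_function <- function(hr_trajectory) {
  if (is.function(hr_trajectory)) return(hr_trajectory)
  if (is.numeric(hr_trajectory) && length(hr_trajectory) == 1) {
    force(hr_trajectory)
    return(function(t) rep(hr_trajectory, length(t)))
  }
  stop("hr_trajectory must be a single bpm value or a function(time_s) -> bpm")
}

#' Linear heart-rate ramp helper
#'
#' Convenience constructor for a heart-rate trajectory ramping linearly from
#' `from` to `to` bpm over `duration` seconds (constant at `to` afterwards).
#'
#' @param from,to Heart rate in bpm at the start and end of the ramp.
#' @param duration Ramp duration in seconds.
#' @return A function of time (seconds) returning bpm.
#' @export
hr_ramp <- function(from, to, duration) {
  function(t) from + (to - from) * pmin(pmax(t / duration, 0), 1)
}

# Evaluate an expression with a temporary RNG state so library-level
# determinism does not disturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
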