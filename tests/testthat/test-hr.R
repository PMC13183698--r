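windowed_tone <- function(hz, fps = 30, secs = 12) {
  t <- (seq_len(secs * fps) - 1) / fps
  bandpass_filter(sin(2 * pi * hz * t), fps)
}

test_that("spectral HR estimates recover pure tones to half a bpm", {
  expect_lt(abs(estimate_hr(windowed_tone(1.2), 30) - 72), 0.5)
  expect_lt(abs(estimate_hr(windowed_tone(0.9), 30) - 54), 0.5)
})

test_that("parabolic interpolation beats the nearest-bin estimate off-grid", {
  fps <- 30; m <- 8192
  # frequency midway between two FFT bins
  k <- 350
  hz <- (k + 0.5) * fps / m
  y <- windowed_tone(hz, fps)
  est <- estimate_hr(y, fps)
  # nearest-bin estimate: recompute the raw periodogram argmax
  p <- abs(stats::fft(c(y, rep(0, m - length(y)))))^2
  freq <- (seq_len(m) - 1) * fps / m
  idx <- which(freq >= 0.65 & freq <= 4)
  nearest <- 60 * freq[idx[which.max(p[idx])]]
  expect_lt(abs(est - 60 * hz), abs(nearest - 60 * hz))
  expect_lt(abs(est - 60 * hz), 0.2)
})

test_that("estimates agree with a 10x finer FFT-grid argmax oracle", {
  fps <- 30
  for (hz in c(0.97, 1.41, 2.23)) {
    y <- windowed_tone(hz, fps)
    est <- estimate_hr(y, fps)
    m <- 81920
    p <- abs(stats::fft(c(y, rep(0, m - length(y)))))^2
    freq <- (seq_len(m) - 1) * fps / m
    idx <- which(freq >= 0.65 & freq <= 4)
    oracle <- 60 * freq[idx[which.max(p[idx])]]
    expect_lt(abs(est - oracle), 0.2)
  }
})

test_that("an all-zero spectrum yields no estimate", {
  expect_true(is.na(estimate_hr(rep(0, 360), 30)))
})

test_that("sliding windows cover whole seconds at 1-s hop", {
  expect_equal(nrow(sliding_windows(68 * 30, 30)), 57)
  w <- sliding_windows(12 * 30, 30)
  expect_equal(nrow(w), 1)
  expect_equal(w$start_frame, 1L)
  expect_equal(w$end_frame, 360L)
  expect_equal(nrow(sliding_windows(11.5 * 30, 30)), 0)
  # timestamps are integral seconds at exactly 1 Hz cadence
  w68 <- sliding_windows(68 * 30, 30)
  expect_equal(w68$window_end_s, 12:68)
})

test_that("reference HR averages the instantaneous channel over the window", {
  ref <- generate_pulse_waveform(60, duration = 20)
  expect_equal(reference_hr(ref, 15), 60)
  ramp <- generate_pulse_waveform(hr_ramp(60, 90, 12), duration = 12)
  expect_equal(reference_hr(ramp, 12), 75, tolerance = 0.15)
  expect_error(reference_hr(ref, 100), "overlap")
})

test_that("reference HR falls back to spectral estimation without an HR channel", {
  ref <- generate_pulse_waveform(84, duration = 14, harmonic2 = 0)
  ref$hr_bpm <- NULL
  expect_lt(abs(reference_hr(ref, 13) - 84), 1)
})

test_that("a clean stationary scene recovers HR within a bpm (generator contract)", {
  cfg <- tiny_scene_config(pulse_amplitude = 3, pixel_noise_sd = 2,
                           seed = 5L)
  rec <- extract_windows(generate_scene(cfg), methods = "GREEN")
  expect_true(all(abs(rec$hr_bpm - 72) <= 1))
})
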