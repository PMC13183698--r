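make_trace <- function(n = 360, fps = 30, hr_hz = 1.2,
                       base = c(120, 140, 110), gains = c(0.33, 1, 0.5),
                       amp = 1) {
  t <- (seq_len(n) - 1) / fps
  p <- sin(2 * pi * hr_hz * t)
  cbind(R = base[1] + gains[1] * amp * p,
        G = base[2] + gains[2] * amp * p,
        B = base[3] + gains[3] * amp * p)
}

test_that("constant traces give all-zero BVP for every method", {
  tr <- matrix(rep(c(100, 120, 90), each = 50), ncol = 3)
  for (m in c("GREEN", "CHROM", "POS")) {
    expect_equal(max(abs(extract_bvp(tr, m))), 0, info = m)
  }
})

test_that("GREEN is the mean-subtracted green channel", {
  tr <- make_trace()
  g <- extract_bvp(tr, "GREEN")
  expect_equal(as.numeric(g), tr[, 2] - mean(tr[, 2]))
  expect_equal(mean(g), 0)
})

test_that("CHROM and POS are invariant to global rescaling; GREEN is not", {
  tr <- make_trace()
  for (m in c("CHROM", "POS")) {
    expect_equal(as.numeric(extract_bvp(tr * 3.7, m)),
                 as.numeric(extract_bvp(tr, m)), tolerance = 1e-10,
                 info = m)
  }
  g1 <- extract_bvp(tr, "GREEN"); g2 <- extract_bvp(tr * 3.7, "GREEN")
  expect_equal(as.numeric(g2), as.numeric(g1) * 3.7, tolerance = 1e-10)
  expect_gt(stats::sd(g2), 2 * stats::sd(g1))
})

test_that("POS annihilates a pure multiplicative intensity modulation", {
  n <- 360; fps <- 30
  t <- (seq_len(n) - 1) / fps
  mod <- 1 + 0.05 * sin(2 * pi * 0.9 * t)
  tr <- cbind(120 * mod, 140 * mod, 110 * mod)
  h <- extract_bvp(tr, "POS")
  expect_lt(stats::sd(h), 1e-10)
})

test_that("CHROM keeps the pulse peak under linear intensity drift", {
  n <- 360; fps <- 30
  t <- (seq_len(n) - 1) / fps
  drift <- 1 + 0.1 * t / max(t)
  tr <- make_trace(n, fps, hr_hz = 1.5, amp = 1)
  trd <- tr * drift
  peak_hz <- function(x) {
    y <- bandpass_filter(as.numeric(x), fps)
    estimate_hr(y, fps) / 60
  }
  expect_lt(abs(peak_hz(extract_bvp(trd, "CHROM")) - 1.5), 0.02)
})

test_that("band-pass removes DC, keeps in-band tones, passes zeros through", {
  fps <- 30; n <- 360
  expect_lt(max(abs(bandpass_filter(rep(5, n), fps))), 1e-8)
  expect_equal(bandpass_filter(rep(0, n), fps), rep(0, n))
  t <- (seq_len(n) - 1) / fps
  y <- bandpass_filter(sin(2 * pi * 1.2 * t), fps)
  expect_lt(abs(estimate_hr(y, fps) - 72), 0.5)
  expect_error(bandpass_filter(sin(t), fps = 7), "Nyquist")
})
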