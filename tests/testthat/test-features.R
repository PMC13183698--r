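test_that("luminance applies BT.601 weights without rounding", {
  expect_equal(luminance(array(100, c(4, 5, 3)))[2, 3], 100)
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(luminance(red)[1, 1], 0.299 * 255)
  expect_equal(luminance(array(0, c(2, 2, 3))), matrix(0, 2, 2))
  expect_error(luminance(matrix(0, 3, 3)), "H x W x 3")
})

test_that("TI is zero for identical frames and uniform brightness steps", {
  expect_equal(temporal_information(gray_frames(5)), 0)
  expect_equal(temporal_information(gray_frames(5, offsets = c(0, 10, 20, 30, 40))), 0)
  expect_error(temporal_information(gray_frames(1)), "2 frames")
})

test_that("a balanced checkerboard difference yields TI = d", {
  d <- 8
  f1 <- array(100, c(6, 6, 3))
  chk <- outer(1:6, 1:6, function(i, j) ifelse((i + j) %% 2 == 0, d, -d))
  f2 <- f1 + array(rep(chk, 3), c(6, 6, 3))
  expect_equal(temporal_information(list(f1, f2)), d, tolerance = 1e-12)
})

test_that("TI equals a brute-force max-over-pairs population sd", {
  set.seed(7)
  frames <- lapply(1:6, function(i) array(runif(60, 0, 255), c(4, 5, 3)))
  lum <- lapply(frames, luminance)
  oracle <- max(vapply(2:6, function(i) {
    m <- lum[[i]] - lum[[i - 1]]
    sqrt(mean((m - mean(m))^2))
  }, numeric(1)))
  expect_equal(temporal_information(frames), oracle, tolerance = 1e-12)
})

test_that("TI is invariant under global additive luminance shifts", {
  set.seed(8)
  frames <- lapply(1:4, function(i) array(runif(48, 50, 150), c(4, 4, 3)))
  shifted <- lapply(seq_along(frames), function(i) frames[[i]] + 5 * i)
  expect_equal(temporal_information(frames), temporal_information(shifted),
               tolerance = 1e-9)
})

test_that("face motion averages per-axis landmark displacements", {
  lmk <- array(0, c(4, 3, 2))
  expect_equal(face_motion(lmk, "x"), 0)
  # +3 px in x per frame for every landmark
  for (i in 1:4) lmk[i, , 1] <- 3 * i
  expect_equal(face_motion(lmk, "x"), 3)
  expect_equal(face_motion(lmk, "y"), 0)
})

test_that("face motion matches the hand-computed l=2, n=3 example", {
  lmk <- array(0, c(3, 2, 2))
  lmk[2, , 1] <- c(1, 2)        # displacements {1, 2}
  lmk[3, , 1] <- c(1 + 3, 2 + 4)  # then {3, 4}
  expect_equal(face_motion(lmk, "x"), (1 + 2 + 3 + 4) / 4)
})

test_that("face motion is offset-invariant and scales linearly", {
  set.seed(9)
  lmk <- array(rnorm(5 * 4 * 2, sd = 3), c(5, 4, 2))
  base <- face_motion(lmk, "x")
  expect_equal(face_motion(lmk + 17.3, "x"), base, tolerance = 1e-12)
  expect_equal(face_motion(lmk * 2.5, "x"), base * 2.5, tolerance = 1e-12)
})

test_that("FM under a sampled sinusoid equals the brute-force mean |diff|", {
  fps <- 30; A <- 4; f <- 1.1
  t <- (0:59) / fps
  x <- A * sin(2 * pi * f * t)
  lmk <- array(0, c(60, 3, 2))
  for (k in 1:3) lmk[, k, 1] <- x
  expect_equal(face_motion(lmk, "x"), mean(abs(diff(x))), tolerance = 1e-12)
})

test_that("FSM averages absolute ROI count changes", {
  expect_equal(face_size_motion(c(100, 110, 90)), 15)
  expect_equal(face_size_motion(c(100, 150)), 50)
  expect_equal(face_size_motion(rep(123, 6)), 0)
  expect_error(face_size_motion(100), "2 frames")
})

test_that("window_features equals recomputing each feature independently", {
  set.seed(10)
  frames <- lapply(1:5, function(i) array(runif(48, 0, 255), c(4, 4, 3)))
  lmk <- array(rnorm(5 * 3 * 2, 50, 4), c(5, 3, 2))
  counts <- c(40, 45, 43, 50, 44)
  wf <- window_features(frames, lmk, counts)
  expect_equal(wf[["TI"]], temporal_information(frames))
  expect_equal(wf[["FM_X"]], face_motion(lmk, "x"))
  expect_equal(wf[["FM_Y"]], face_motion(lmk, "y"))
  expect_equal(wf[["FSM"]], face_size_motion(counts))
  expect_true(all(wf >= 0))
})
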