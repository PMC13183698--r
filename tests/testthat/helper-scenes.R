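# Small scene configurations shared across tests. Kept tiny so unit tests
# render in well under a second each.

tiny_scene_config <- function(...) {
  args <- utils::modifyList(
    list(width = 96, height = 72, fps = 20, duration = 14,
         hr_trajectory = 72, pulse_amplitude = 4,
         pixel_noise_sd = 0, tracking_lag = 0, tracking_jitter = 0),
    list(...))
  do.call(scene_config, args)
}

# A mid-sized clean scene used for HR-recovery checks.
recovery_scene_config <- function(hr, ...) {
  args <- utils::modifyList(
    list(width = 160, height = 120, fps = 30, duration = 16,
         hr_trajectory = hr, pulse_amplitude = 4,
         pixel_noise_sd = 1.5, tracking_lag = 0, tracking_jitter = 0),
    list(...))
  do.call(scene_config, args)
}

# Uniform gray frame stack with optional per-frame offsets.
gray_frames <- function(n, h = 8, w = 10, value = 100, offsets = NULL) {
  lapply(seq_len(n), function(i) {
    v <- value + if (is.null(offsets)) 0 else offsets[i]
    array(v, dim = c(h, w, 3))
  })
}

# Brute-force point-in-convex-polygon rasterizer used as the ROI oracle.
brute_hull_count <- function(pts, width, height) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  count <- 0L
  for (x in 0:(width - 1)) {
    for (y in 0:(height - 1)) {
      signs <- vapply(seq_len(n), function(k) {
        p1 <- hull[k, ]; p2 <- hull[(k %% n) + 1, ]
        (p2[1] - p1[1]) * (y - p1[2]) - (p2[2] - p1[2]) * (x - p1[1])
      }, numeric(1))
      if (all(signs <= 1e-9) || all(signs >= -1e-9)) count <- count + 1L
    }
  }
  count
}

# Brute-force pairwise AUC oracle (ties count one half).
brute_auc <- function(scores, labels) {
  s_pos <- scores[labels == 1]
  s_neg <- scores[labels == 0]
  tot <- 0
  for (p in s_pos) for (q in s_neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(s_pos) * length(s_neg))
}
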