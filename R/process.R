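#' Per-frame statistics for a video
#'
#' Single streaming pass over a frame sequence with aligned landmarks,
#' computing everything the windowed stages need: the luminance-difference
#' standard deviation for each consecutive frame pair (the TI building
#' block), and the ROI pixel count and ROI-mean RGB triplet per frame. The
#' ROI is the convex hull of the face landmarks minus the eye and mouth
#' hulls (see [rasterize_roi()]).
#'
#' @param frames List of H x W x 3 arrays.
#' @param landmarks n x l x 2 landmark array aligned to `frames`.
#' @param groups Named list of landmark index vectors with a `face` entry;
#'   all other entries are exclusion hulls. Defaults to the synthetic-scene
#'   layout.
#' @return Data frame with one row per frame: `frame`, `ti_sigma` (sd of the
#'   luminance difference to the previous frame; `NA` for the first frame),
#'   `N` (ROI pixel count), `R`, `G`, `B` (ROI channel means), `roi_ok`.
#' @export
video_frame_stats <- function(frames, landmarks, groups = landmark_groups()) {
  n <- length(frames)
  stopifnot(n >= 2, dim(landmarks)[1] == n)
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  ti_sigma <- rep(NA_real_, n)
  N <- integer(n)
  rgb <- matrix(NA_real_, n, 3)
  roi_ok <- logical(n)
  excl_names <- setdiff(names(groups), "face")
  prev_luma <- NULL
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    luma <- luminance(fr)
    if (i > 1) ti_sigma[i] <- sd_pop(luma - prev_luma)
    prev_luma <- luma
    pts <- landmarks[i, , , drop = TRUE]
    roi <- tryCatch(
      rasterize_roi(pts[groups$face, , drop = FALSE],
                    lapply(excl_names,
                           function(g) pts[groups[[g]], , drop = FALSE]),
                    width = w, height = h),
      error = function(e) NULL)
    if (!is.null(roi) && roi$count > 0) {
      N[i] <- roi$count
      rgb[i, ] <- channel_means(fr, roi$mask)
      roi_ok[i] <- TRUE
    }
  }
  data.frame(frame = seq_len(n), ti_sigma = ti_sigma, N = N,
             R = rgb[, 1], G = rgb[, 2], B = rgb[, 3], roi_ok = roi_ok)
}

#' Extract per-window heart rates and motion features from a video
#'
#' Runs the full windowed pipeline on one video: 12-s sliding windows at 1-s
#' hop; per window, the four motion features (TI, FM_X, FM_Y, FSM), the
#' heart rate from each requested BVP method (band-pass + Hann + spectral
#' peak with parabolic interpolation), the reference heart rate, and the
#' absolute error. Windows containing any frame with an empty or degenerate
#' ROI yield no estimate (`hr_bpm = NA`, reason `"no_roi"`) rather than an
#' interpolated one.
#'
#' @param frames List of frames, or an `rppg_scene` (in which case
#'   `landmarks`, `fps` and `reference` are taken from the scene).
#' @param landmarks n x l x 2 landmark array.
#' @param fps Frame rate.
#' @param reference Optional reference trace (`time_s`, `ppg`, `hr_bpm`);
#'   when absent, reference columns are `NA`.
#' @param methods BVP methods to run (default all three).
#' @param window_s,hop_s Window length and hop in seconds.
#' @param band,order Passband (Hz) and order of the Butterworth filter.
#' @param video_id,subject_id,dataset_id Identifier columns for the output.
#' @param groups Landmark group layout (see [video_frame_stats()]).
#' @return Data frame with one row per window per method: identifiers,
#'   `window_end_s`, `method`, `TI`, `FM_X`, `FM_Y`, `FSM`, `hr_bpm`,
#'   `hr_ref_bpm`, `abs_err_bpm`, `reason`.
#' @export
extract_windows <- function(frames, landmarks = NULL, fps = NULL,
                            reference = NULL,
                            methods = c("GREEN", "CHROM", "POS"),
                            window_s = 12, hop_s = 1,
                            band = c(0.65, 4), order = 6,
                            video_id = "video", subject_id = "subject",
                            dataset_id = "dataset",
                            groups = landmark_groups()) {
  if (inherits(frames, "rppg_scene")) {
    scene <- frames
    frames <- scene$frames
    landmarks <- scene$landmarks
    fps <- scene$fps
    if (is.null(reference)) reference <- scene$reference
    groups <- scene$landmark_groups
  }
  stopifnot(!is.null(landmarks), !is.null(fps))
  methods <- match.arg(methods, several.ok = TRUE)
  stats <- video_frame_stats(frames, landmarks, groups)
  windows_from_stats(stats, landmarks, fps, reference, methods,
                     window_s, hop_s, band, order,
                     video_id, subject_id, dataset_id)
}

# Windowed stage, separated so precomputed per-frame stats can be reused.
windows_from_stats <- function(stats, landmarks, fps, reference, methods,
                               window_s = 12, hop_s = 1,
                               band = c(0.65, 4), order = 6,
                               video_id = "video", subject_id = "subject",
                               dataset_id = "dataset") {
  n <- nrow(stats)
  wins <- sliding_windows(n, fps, window_s, hop_s)
  out <- vector("list", nrow(wins))
  if (nrow(wins) == 0) return(empty_window_df())
  for (j in seq_len(nrow(wins))) {
    s <- wins$start_frame[j]; e <- wins$end_frame[j]
    idx <- s:e
    feats <- c(TI = max(stats$ti_sigma[(s + 1):e]),
               FM_X = face_motion(landmarks[idx, , , drop = FALSE], "x"),
               FM_Y = face_motion(landmarks[idx, , , drop = FALSE], "y"),
               FSM = face_size_motion(stats$N[idx]))
    ref <- if (is.null(reference)) NA_real_ else
      reference_hr(reference, wins$window_end_s[j], window_s)
    rows <- lapply(methods, function(m) {
      hr <- NA_real_; reason <- ""
      if (!all(stats$roi_ok[idx])) {
        reason <- "no_roi"
      } else {
        trace <- as.matrix(stats[idx, c("R", "G", "B")])
        hr <- tryCatch({
          bvp <- extract_bvp(trace, m)
          estimate_hr(bandpass_filter(bvp, fps, band, order), fps, band)
        }, error = function(e) NA_real_)
        if (is.na(hr)) reason <- "no_estimate"
      }
      data.frame(video_id = video_id, subject_id = subject_id,
                 dataset_id = dataset_id,
                 window_end_s = wins$window_end_s[j], method = m,
                 TI = feats[["TI"]], FM_X = feats[["FM_X"]],
                 FM_Y = feats[["FM_Y"]], FSM = feats[["FSM"]],
                 hr_bpm = hr, hr_ref_bpm = ref,
                 abs_err_bpm = abs(hr - ref), reason = reason,
                 stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

empty_window_df <- function() {
  data.frame(video_id = character(0), subject_id = character(0),
             dataset_id = character(0), window_end_s = numeric(0),
             method = character(0), TI = numeric(0), FM_X = numeric(0),
             FM_Y = numeric(0), FSM = numeric(0), hr_bpm = numeric(0),
             hr_ref_bpm = numeric(0), abs_err_bpm = numeric(0),
             reason = character(0), stringsAsFactors = FALSE)
}
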