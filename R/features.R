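#' Per-pixel luminance of an RGB frame
#'
#' Converts an 8-bit RGB frame to real-valued luminance using BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B). No rounding is applied: downstream
#' temporal-difference statistics operate on unrounded values.
#'
#' @param frame An H x W x 3 numeric array (8-bit values).
#' @return An H x W numeric luminance matrix.
#' @examples
#' f <- array(100, dim = c(4, 4, 3))
#' luminance(f)[1, 1]
#' @export
luminance <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3) stop("frame must be an H x W x 3 array")
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# Population standard deviation (divisor N, not N-1), as used for the
# temporal-difference statistic.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Temporal perceptual information (TI) of a frame sequence
#'
#' The scene-motion metric of ITU-T Rec. P.910: for each consecutive frame
#' pair, the spatial (population) standard deviation of the luminance
#' difference image is computed over the full frame; TI is the maximum over
#' all pairs in the sequence. A uniform brightness change over the whole
#' frame therefore contributes nothing, while spatially structured change
#' (motion) does.
#'
#' @param frames A list of H x W x 3 arrays (at least 2).
#' @return TI, a nonnegative scalar in luminance units.
#' @export
temporal_information <- function(frames) {
  if (length(frames) < 2) stop("TI requires at least 2 frames")
  max(ti_sigmas(frames))
}

# sigma[M_i] for each consecutive pair; shared by temporal_information()
# and the streaming video pass.
ti_sigmas <- function(frames) {
  prev <- luminance(frames[[1]])
  vapply(seq.int(2, length(frames)), function(i) {
    cur <- luminance(frames[[i]])
    s <- sd_pop(cur - prev)
    prev <<- cur
    s
  }, numeric(1))
}

#' Face motion along one axis (FM_X / FM_Y)
#'
#' Mean absolute per-frame displacement of the facial landmarks along the
#' x or y axis: the sum of |displacement| over all l landmarks and all n-1
#' consecutive frame pairs, divided by l (n - 1).
#'
#' @param landmarks An n x l x 2 array of landmark coordinates (x, y) in px,
#'   frames in order.
#' @param axis `"x"` or `"y"`.
#' @return FM along the requested axis, px per frame step.
#' @export
face_motion <- function(landmarks, axis = c("x", "y")) {
  axis <- match.arg(axis)
  d <- dim(landmarks)
  if (length(d) != 3 || d[3] != 2) stop("landmarks must be an n x l x 2 array")
  if (d[1] < 2) stop("face motion requires at least 2 frames")
  if (any(!is.finite(landmarks))) stop("landmark coordinates must be finite")
  k <- if (axis == "x") 1L else 2L
  coords <- landmarks[, , k, drop = TRUE]
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  mean(abs(diff(coords)))
}

#' Face size motion (FSM)
#'
#' Mean absolute per-frame change in the ROI pixel count, a proxy for
#' displacement along the z axis (toward/away from the camera).
#'
#' @param roi_pixel_counts Integer vector of per-frame ROI pixel counts N_i.
#' @return FSM in pixels per frame step.
#' @export
face_size_motion <- function(roi_pixel_counts) {
  n <- length(roi_pixel_counts)
  if (n < 2) stop("FSM requires at least 2 frames")
  if (any(roi_pixel_counts < 0)) stop("pixel counts must be nonnegative")
  mean(abs(diff(roi_pixel_counts)))
}

#' All four motion features for one analysis window
#'
#' Bundles [temporal_information()], [face_motion()] along x and y, and
#' [face_size_motion()] for a window of frames with aligned landmarks and
#' ROI pixel counts.
#'
#' @param frames List of H x W x 3 arrays for the window.
#' @param landmarks n x l x 2 landmark array aligned to `frames`.
#' @param roi_pixel_counts Per-frame ROI pixel counts aligned to `frames`.
#' @return Named numeric vector `c(TI, FM_X, FM_Y, FSM)`.
#' @export
window_features <- function(frames, landmarks, roi_pixel_counts) {
  n <- length(frames)
  if (dim(landmarks)[1] != n || length(roi_pixel_counts) != n) {
    stop("frames, landmarks and roi_pixel_counts must cover the same frames")
  }
  c(TI = temporal_information(frames),
    FM_X = face_motion(landmarks, "x"),
    FM_Y = face_motion(landmarks, "y"),
    FSM = face_size_motion(roi_pixel_counts))
}
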