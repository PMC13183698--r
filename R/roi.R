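#' Rasterize the skin region of interest from facial landmarks
#'
#' Builds the per-frame skin mask: the convex hull of the face landmarks,
#' rasterized over the pixel grid, minus the convex hulls of each exclusion
#' point set (eyes, mouth). Pixel coordinates are 0-based with x = column
#' and y = row, origin top-left; a pixel belongs to a hull when its center
#' lies strictly inside or on the hull boundary (tolerance 1e-9).
#'
#' @param face_points An m x 2 matrix of (x, y) landmark coordinates,
#'   m >= 3, not all collinear.
#' @param exclusions Optional list of point matrices whose hulls are
#'   subtracted from the face hull.
#' @param width,height Frame size in pixels; the mask is clipped to
#'   `[0, width-1] x [0, height-1]`.
#' @return A list with `mask` (height x width logical matrix) and `count`
#'   (number of TRUE pixels).
#' @examples
#' sq <- cbind(c(0, 0, 10, 10), c(0, 10, 0, 10))
#' rasterize_roi(sq, width = 20, height = 20)$count  # 121
#' @export
rasterize_roi <- function(face_points, exclusions = list(),
                          width, height) {
  mask <- hull_mask(face_points, width, height)
  for (ex in exclusions) {
    if (nrow(ex) >= 3) mask <- mask & !hull_mask(ex, width, height)
  }
  list(mask = mask, count = sum(mask))
}

# Rasterize the convex hull of a point set as a logical H x W matrix.
# Evaluates the half-plane test only inside the hull's bounding box.
hull_mask <- function(pts, width, height) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) stop("need at least 3 points")
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3 || polygon_area2(hull) == 0) {
    stop("degenerate (collinear) hull")
  }
  mask <- matrix(FALSE, height, width)
  x0 <- max(0L, floor(min(hull[, 1])))
  x1 <- min(width - 1L, ceiling(max(hull[, 1])))
  y0 <- max(0L, floor(min(hull[, 2])))
  y1 <- min(height - 1L, ceiling(max(hull[, 2])))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1
  ys <- y0:y1
  xg <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  yg <- matrix(ys, length(ys), length(xs))
  inside <- matrix(TRUE, length(ys), length(xs))
  # chull returns vertices clockwise in standard orientation; orient by the
  # signed area so the test works either way.
  s <- sign(polygon_area2(hull))
  nh <- nrow(hull)
  for (k in seq_len(nh)) {
    p1 <- hull[k, ]
    p2 <- hull[if (k == nh) 1L else k + 1L, ]
    cr <- (xg - p1[1]) * (p2[2] - p1[2]) - (yg - p1[2]) * (p2[1] - p1[1])
    inside <- inside & (s * cr <= 1e-9)
  }
  mask[ys + 1L, xs + 1L] <- inside
  mask
}

# Twice the signed area of a polygon (shoelace).
polygon_area2 <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

#' Mean RGB within a mask
#'
#' Averages each color channel of a frame over the masked pixels.
#'
#' @param frame H x W x 3 numeric array.
#' @param mask H x W logical matrix.
#' @return Named numeric vector `c(R, G, B)` of channel means.
#' @export
channel_means <- function(frame, mask) {
  if (!any(mask)) {
    stop("empty ROI mask: no skin pixels in frame", call. = FALSE)
  }
  c(R = mean(frame[, , 1][mask]),
    G = mean(frame[, , 2][mask]),
    B = mean(frame[, , 3][mask]))
}
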