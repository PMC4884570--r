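# Feret-diameter geometry on region boundaries.
#
# All boundary points are (x, y) in pixel coordinates with the origin at the
# top-left of the frame and y increasing downwards (image convention).
# Orientations are reported in degrees in [0, 180), measured from the image
# horizontal, counterclockwise positive in the usual mathematical sense:
# internally every direction computation flips the y axis (y_up = -y) so that
# a chord running from bottom-left to top-right has a positive angle.

# Convex hull of a two-column point matrix (already in y-up coordinates),
# counterclockwise, with duplicate points removed first.
hull_ccw <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3L) {
    return(pts)
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  # chull() returns vertices clockwise; reverse for counterclockwise.
  h <- pts[rev(idx), , drop = FALSE]
  # guard: enforce counterclockwise orientation whatever chull returned
  n <- nrow(h)
  j <- c(n, seq_len(n - 1L))
  signed2 <- sum(h[j, 1] * h[, 2] - h[, 1] * h[j, 2])
  if (signed2 < 0) h <- h[rev(seq_len(n)), , drop = FALSE]
  h
}

cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

# Rotating-calipers enumeration of antipodal vertex pairs of a convex polygon
# (counterclockwise, y-up coordinates). Returns an m x 2 matrix of vertex
# index pairs; the polygon diameter is attained on one of them.
antipodal_pairs <- function(h) {
  n <- nrow(h)
  if (n == 2L) return(matrix(c(1L, 2L), 1L))
  nxt <- function(i) i %% n + 1L
  pairs <- vector("list", 3L * n)
  np <- 0L
  push <- function(i, j) {
    np <<- np + 1L
    pairs[[np]] <<- c(i, j)
  }
  j <- 2L
  for (i in seq_len(n)) {
    i2 <- nxt(i)
    # advance j while the triangle on edge (i, i2) keeps growing
    repeat {
      j2 <- nxt(j)
      a_next <- cross2(h[i, 1], h[i, 2], h[i2, 1], h[i2, 2], h[j2, 1], h[j2, 2])
      a_cur <- cross2(h[i, 1], h[i, 2], h[i2, 1], h[i2, 2], h[j, 1], h[j, 2])
      if (a_next > a_cur && j2 != i) {
        j <- j2
      } else {
        # parallel edge: the next vertex is equally far from this edge
        if (a_next == a_cur) {
          push(i, j2)
          push(i2, j2)
        }
        break
      }
    }
    push(i, j)
    push(i2, j)
  }
  do.call(rbind, pairs[seq_len(np)])
}

# Maximum Feret diameter of a point set: the greatest pairwise distance,
# computed on the convex hull by rotating calipers. y-up flip applied here.
feret_max <- function(pts) {
  if (nrow(pts) < 3L) abort("need at least 3 boundary points")
  h <- hull_ccw(cbind(pts[, 1], -pts[, 2]))
  if (nrow(h) < 2L) abort("degenerate boundary: all points coincide")
  cand <- antipodal_pairs(h)
  dx <- h[cand[, 1], 1] - h[cand[, 2], 1]
  dy <- h[cand[, 1], 2] - h[cand[, 2], 2]
  d2 <- dx * dx + dy * dy
  dmax <- max(d2)
  # tie-break among (numerically) equal-length chords: smallest folded angle
  ties <- which(d2 >= dmax * (1 - 1e-12))
  ang <- fold_angle(atan2(dy[ties], dx[ties]) * 180 / pi)
  k <- ties[which.min(ang)]
  list(
    length_px = sqrt(d2[k]),
    angle_deg = min(ang),
    from = c(h[cand[k, 1], 1], -h[cand[k, 1], 2]),
    to = c(h[cand[k, 2], 1], -h[cand[k, 2], 2])
  )
}

# Feret extent (projection width) of a point set along a direction in
# degrees. Vectorised over `direction_deg`.
feret_extent <- function(pts, direction_deg) {
  th <- direction_deg * pi / 180
  u <- rbind(cos(th), sin(th))          # y-up direction
  proj <- cbind(pts[, 1], -pts[, 2]) %*% u
  apply(proj, 2L, function(p) max(p) - min(p))
}

#' Convert a pixel length to micrometers
#'
#' Multiplies a length measured in pixels by the per-image pixel scale. The
#' default scale, 6.579 um/pixel, corresponds to a 2 x 2 mm en-face frame
#' sampled with 304 x 304 A-scans.
#'
#' @param length_px Length in pixels (non-negative, vectorised).
#' @param um_per_pixel Pixel scale in micrometers per pixel (> 0).
#' @return Length in micrometers.
#' @examples
#' px_to_um(100)           # 657.9
#' px_to_um(304, 6.579)    # 2000.016, the full frame width
#' @export
px_to_um <- function(length_px, um_per_pixel = 6.579) {
  if (any(length_px < 0, na.rm = TRUE)) abort("`length_px` must be non-negative")
  check_number(um_per_pixel, "um_per_pixel", min = .Machine$double.eps)
  length_px * um_per_pixel
}

#' Classify a maximum-diameter orientation as typical or atypical
#'
#' An orientation within 15 degrees (inclusive) of the horizontal (0) or
#' vertical (90) image axis is "typical"; anything else is "atypical". In
#' healthy eyes the FAZ is an axis-aligned oval, so its maximum diameter
#' lies near one of the two axes; gap-broken diabetic FAZ shapes usually do
#' not. Distances are taken on the half-circle, so 165-180 degrees is within
#' 15 degrees of the horizontal.
#'
#' @param angle_deg Orientation(s) in degrees; folded into [0, 180).
#' @param tolerance_deg Half-width of the typical band around each axis
#'   (degrees, default 15; the boundary is inclusive).
#' @return Character vector, `"typical"` or `"atypical"`.
#' @examples
#' classify_angle(c(0, 15, 45, 90, 105, 165))
#' @export
classify_angle <- function(angle_deg, tolerance_deg = 15) {
  check_number(tolerance_deg, "tolerance_deg", min = 0, max = 45)
  a <- fold_angle(angle_deg)
  d <- pmin(orientation_distance(a, 0), orientation_distance(a, 90))
  ifelse(d <= tolerance_deg, "typical", "atypical")
}

#' Maximum Feret diameter of a FAZ region
#'
#' The greatest distance between any two boundary points, computed on the
#' convex hull of the boundary polygon by rotating calipers, together with
#' the orientation of that chord. Among chords of (numerically) equal
#' length the smallest orientation wins, which makes results on symmetric
#' regions deterministic.
#'
#' @param region A [faz_region] object.
#' @return A one-row tibble with `length_um`, `length_px` and `angle_deg`
#'   (degrees in [0, 180), 0 = image horizontal).
#' @seealso [directional_diameter()], [classify_angle()]
#' @export
max_diameter <- function(region) {
  stopifnot(inherits(region, "faz_region"))
  fm <- feret_max(region$boundary)
  tibble(
    length_um = px_to_um(fm$length_px, region$um_per_pixel),
    length_px = fm$length_px,
    angle_deg = fm$angle_deg
  )
}

#' Feret extent of a FAZ region along a direction
#'
#' Width of the projection of the region boundary onto a unit vector at the
#' given orientation: the caliper distance across the region in that
#' direction. The horizontal diameter is the extent at 0 degrees, the
#' vertical at 90, and the "diameter at 90 degrees to the maximum" is the
#' extent perpendicular to the maximum-diameter chord.
#'
#' @param region A [faz_region] object.
#' @param direction_deg Direction(s) in degrees (0 = image horizontal).
#' @return Extent(s) in micrometers.
#' @export
directional_diameter <- function(region, direction_deg) {
  stopifnot(inherits(region, "faz_region"))
  if (nrow(region$boundary) < 3L) abort("need at least 3 boundary points")
  px_to_um(feret_extent(region$boundary, direction_deg), region$um_per_pixel)
}
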