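# FAZ region extraction from an en-face angiogram.

#' Construct a FAZ region from a boundary polygon
#'
#' Mostly used internally by [extract_faz()], but also handy for geometric
#' tests and for measuring analytically defined shapes: any simple polygon
#' in pixel coordinates (x right, y down) can be wrapped into a region and
#' pushed through [max_diameter()] and [directional_diameter()].
#'
#' @param boundary Two-column matrix of boundary points `(x, y)` in pixels.
#' @param um_per_pixel Pixel scale (micrometers per pixel).
#' @param mask Optional logical matrix of the region (true = avascular).
#' @param eye_id,layer Optional identifiers carried through to measurements.
#' @return An object of class `faz_region`.
#' @export
faz_region <- function(boundary, um_per_pixel = 6.579, mask = NULL,
                       eye_id = "region", layer = "superficial") {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2L || nrow(boundary) < 3L) {
    abort("`boundary` must be an n x 2 matrix with n >= 3")
  }
  check_number(um_per_pixel, "um_per_pixel", min = .Machine$double.eps)
  structure(
    list(
      boundary = unname(boundary),
      mask = mask,
      centroid = polygon_centroid(boundary),
      area_px2 = polygon_area(boundary),
      um_per_pixel = um_per_pixel,
      eye_id = eye_id,
      layer = layer
    ),
    class = "faz_region"
  )
}

#' @export
print.faz_region <- function(x, ...) {
  cat(sprintf(
    "<faz_region> %s (%s): area %.0f um^2, centroid (%.1f, %.1f) px, %d boundary points\n",
    x$eye_id, x$layer, x$area_px2 * x$um_per_pixel^2,
    x$centroid[1], x$centroid[2], nrow(x$boundary)))
  invisible(x)
}

#' Extract the foveal avascular zone from an angiogram
#'
#' Binarises the flow signal at `vessel_threshold`, morphologically closes
#' the vessel mask (bridging sub-capillary noise but not true arcade gaps),
#' and takes the avascular 4-connected component containing the frame
#' centre as the FAZ. The region boundary is extracted sub-pixel: the
#' component mask is Gaussian-smoothed and traced with a marching-squares
#' contour at level 0.5, which removes most of the half-pixel staircase
#' bias of a binary rasterisation.
#'
#' @param image A [faz_angiogram] object.
#' @param vessel_threshold Intensity above which a pixel counts as vessel
#'   (same scale as the image, default 0.35; the synthetic renderer
#'   guarantees a plateau so any value in (0.25, 0.5] gives the same mask).
#' @param closing_radius_px Radius of the disc used to morphologically
#'   close the vessel mask (pixels; 0 disables closing).
#' @param boundary_sigma Standard deviation of the Gaussian used to smooth
#'   the component mask before contour tracing (pixels).
#' @return A [faz_region] object.
#' @section Errors:
#' Aborts when the centre pixel lies on a vessel after closing (off-centre
#' fixation), when the FAZ component touches the frame border (region not
#' fully imaged; an all-background frame also ends up here), or when the
#' component covers more than half the frame (degenerate mask).
#' @export
extract_faz <- function(image, vessel_threshold = 0.35,
                        closing_radius_px = 2L, boundary_sigma = 3) {
  stopifnot(inherits(image, "faz_angiogram"))
  check_number(vessel_threshold, "vessel_threshold", min = 0, max = 1)
  check_number(closing_radius_px, "closing_radius_px", min = 0, max = 25)
  res <- nrow(image$pixels)
  vessel <- image$pixels > vessel_threshold
  if (closing_radius_px >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
    vessel <- EBImage::closing(vessel, brush) > 0
  }
  cc <- as.integer(round((res + 1) / 2))
  if (vessel[cc, cc]) {
    abort("centre pixel lies on a vessel after closing: off-centre fixation; cannot seed the FAZ")
  }
  free <- (!vessel) * 1
  filled <- EBImage::floodFill(free, c(cc, cc), col = 2)
  mask <- filled == 2
  if (any(mask[1, ]) || any(mask[res, ]) || any(mask[, 1]) || any(mask[, res])) {
    abort("FAZ touches the frame border: region not fully imaged")
  }
  if (sum(mask) > 0.5 * res * res) {
    abort("candidate FAZ covers more than half the frame: degenerate vessel mask")
  }
  sm <- EBImage::gblur(mask * 1, sigma = boundary_sigma)
  cl <- contourLines(x = seq_len(res), y = seq_len(res), z = sm, levels = 0.5)
  if (length(cl) == 0L) abort("no boundary contour found")
  # contourLines: $x follows matrix rows (image y), $y follows columns (x)
  polys <- lapply(cl, function(ct) cbind(x = ct$y, y = ct$x))
  areas <- vapply(polys, polygon_area, numeric(1))
  boundary <- polys[[which.max(areas)]]
  faz_region(boundary, image$um_per_pixel, mask = mask,
             eye_id = image$eye_id, layer = image$layer)
}
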