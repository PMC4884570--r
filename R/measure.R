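# From angiogram to the five diameters and the angle class.

#' Measure one angiogram
#'
#' Runs [extract_faz()] and computes the full measurement record: the
#' horizontal and vertical Feret extents, the maximum Feret diameter and
#' its orientation, the extent perpendicular to the maximum, and the
#' typical/atypical angle class.
#'
#' @param image A [faz_angiogram] object.
#' @inheritParams extract_faz
#' @param region Optionally, a pre-extracted [faz_region] (skips
#'   extraction).
#' @return A one-row tibble: `eye_id`, `layer`, `horizontal_um`,
#'   `vertical_um`, `max_um`, `perp_um`, `angle_deg`, `angle_class`,
#'   `area_um2`.
#' @examples
#' gt <- sample_cohort(cohort_params(seed = 1))[1, ]
#' measure_angiogram(render_angiogram(gt))
#' @export
measure_angiogram <- function(image, vessel_threshold = 0.35,
                              closing_radius_px = 2L, boundary_sigma = 3,
                              region = NULL) {
  if (is.null(region)) {
    region <- extract_faz(image, vessel_threshold, closing_radius_px, boundary_sigma)
  }
  md <- max_diameter(region)
  ext <- directional_diameter(region, c(0, 90, md$angle_deg + 90))
  tibble(
    eye_id = region$eye_id,
    layer = region$layer,
    horizontal_um = ext[1],
    vertical_um = ext[2],
    max_um = md$length_um,
    perp_um = ext[3],
    angle_deg = md$angle_deg,
    angle_class = classify_angle(md$angle_deg),
    area_um2 = region$area_px2 * region$um_per_pixel^2
  )
}

#' Render and measure a whole synthetic cohort
#'
#' For every row of a [sample_cohort()] tibble, renders the angiogram and
#' measures it. The imaged field widens automatically for eyes whose FAZ
#' would not fit a 2 mm frame (the pixel scale is per-image metadata, so
#' measurements stay in micrometers regardless). Eyes whose extraction
#' fails are dropped with a warning and counted in the `excluded`
#' attribute.
#'
#' @param cohort Tibble from [sample_cohort()].
#' @param resolution Frame side in pixels.
#' @param field_um Base field width in micrometers (default 2 mm at the
#'   6.579 um/px scale); widened per eye when the ellipse needs more room.
#' @inheritParams extract_faz
#' @param ... Further arguments passed to [render_angiogram()].
#' @return Tibble of measurements (one row per rendered eye) joined with
#'   `group`, `typical` (the assigned stratum) and `bcva`; the number of
#'   excluded eyes is attached as `attr(, "excluded")`.
#' @export
measure_cohort <- function(cohort, resolution = 304L,
                           field_um = 6.579 * resolution,
                           vessel_threshold = 0.35, closing_radius_px = 2L,
                           boundary_sigma = 3, ...) {
  stopifnot(is.data.frame(cohort))
  rows <- vector("list", nrow(cohort))
  failed <- character(0)
  for (i in seq_len(nrow(cohort))) {
    gt <- cohort[i, ]
    # ellipse (plus gap reach) must keep a 10% margin; widen field if needed
    reach <- gt$faz_semi_major + ifelse(gt$n_gaps > 0, 60, 0)
    fld <- max(field_um, reach / 0.38)
    rows[[i]] <- tryCatch({
      img <- render_angiogram(gt, resolution = resolution, field_um = fld, ...)
      m <- measure_angiogram(img, vessel_threshold, closing_radius_px, boundary_sigma)
      m$group <- gt$group
      m$typical <- gt$typical
      m$bcva <- gt$bcva
      m
    }, error = function(e) {
      failed <<- c(failed, sprintf("%s/%s: %s", gt$eye_id, gt$layer, conditionMessage(e)))
      NULL
    })
  }
  out <- dplyr::bind_rows(rows)
  if (length(failed) > 0L) {
    warn(sprintf("excluded %d eye(s) with failed extraction", length(failed)))
  }
  attr(out, "excluded") <- failed
  out
}
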