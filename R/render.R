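# Synthetic en-face angiogram rendering.
#
# The generator emulates the features a grader sees on an en-face OCT-A
# frame: a central avascular ellipse (the FAZ), a closed perifoveal arcade
# drawn as a thin ring hugging the ellipse from outside, and a surrounding
# capillary mesh built from a jittered square lattice. Diabetic eyes get
# arcade gaps (angular sectors in which the arcade and the nearby mesh are
# erased, so the avascular region grows through the gap into a shallow
# pocket) and random deletion of mesh edges away from the arcade (capillary
# dropout). Intensities are bimodal by construction - background in
# [0.02, 0.22], vessels in [0.55, 0.95] - so any binarisation threshold on
# the plateau in between yields the same vessel mask.

# cached per-resolution pixel coordinate matrices (X = column, Y = row)
.render_cache <- new.env(parent = emptyenv())

pixel_grid <- function(resolution) {
  key <- as.character(resolution)
  g <- .render_cache[[key]]
  if (is.null(g)) {
    X <- matrix(rep(seq_len(resolution), each = resolution), resolution)
    Y <- matrix(rep(seq_len(resolution), resolution), resolution)
    g <- list(X = X, Y = Y)
    .render_cache[[key]] <- g
  }
  g
}

#' Construct an en-face angiogram object
#'
#' @param pixels Numeric matrix in [0, 1]; 0 = no flow signal.
#' @param um_per_pixel Pixel scale (micrometers per pixel, > 0).
#' @param layer `"superficial"` or `"deep"`.
#' @param eye_id Identifier string.
#' @return An object of class `faz_angiogram`.
#' @export
faz_angiogram <- function(pixels, um_per_pixel, layer = "superficial", eye_id = "eye") {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  check_number(um_per_pixel, "um_per_pixel", min = .Machine$double.eps)
  structure(
    list(pixels = pixels, um_per_pixel = um_per_pixel,
         layer = layer, eye_id = eye_id),
    class = "faz_angiogram"
  )
}

#' @export
print.faz_angiogram <- function(x, ...) {
  cat(sprintf("<faz_angiogram> %s (%s layer), %d x %d px at %.3f um/px\n",
              x$eye_id, x$layer, nrow(x$pixels), ncol(x$pixels), x$um_per_pixel))
  invisible(x)
}

#' Render a synthetic en-face angiogram for one eye
#'
#' Rasterises the ground-truth FAZ ellipse of one sampled eye into a square
#' grayscale frame. See the package vignette for the network model and its
#' defaults. Rendering is fully deterministic given `gt$render_seed`.
#'
#' @param gt One-row data frame (or list) with the ground-truth fields
#'   produced by [sample_cohort()]: `faz_semi_major`, `faz_semi_minor`
#'   (micrometers), `faz_orientation` (degrees), `n_gaps`, `gap_arc`,
#'   `dropout_fraction`, `render_seed`, and optionally `eye_id`, `layer`.
#' @param resolution Frame side length in pixels (default 304).
#' @param field_um Imaged field width in micrometers. The default,
#'   `6.579 * resolution`, reproduces a 2 x 2 mm protocol at 304 px. The FAZ
#'   ellipse (plus gap depth) must fit inside the frame with a margin of at
#'   least 10 % of the field, otherwise an error is thrown; callers imaging
#'   large deep-layer FAZs should widen the field (see [measure_cohort()]).
#' @param node_spacing_um Capillary-mesh lattice spacing (micrometers).
#' @param vessel_brush_px Diameter of the dilation brush applied to the
#'   1-pixel rasterised mesh; the resulting vessel thickness is 1-3 px.
#' @param ring_um Radial thickness of the perifoveal arcade ring
#'   (micrometers, drawn outward from the ellipse boundary so the avascular
#'   interior keeps exactly the ground-truth extent).
#' @param gap_depth_um Radial depth to which arcade gaps erase vessels
#'   beyond the ellipse boundary (micrometers). Gaps are shallow notches:
#'   they enlarge the avascular area without materially changing its Feret
#'   extents.
#' @param n_shadows Number of circular signal-void (shadowing) artifacts to
#'   place outside the perifoveal region (default 0).
#' @return A [faz_angiogram] object.
#' @examples
#' gt <- sample_cohort(cohort_params(seed = 1))[1, ]
#' img <- render_angiogram(gt)
#' @export
render_angiogram <- function(gt,
                             resolution = 304L,
                             field_um = 6.579 * resolution,
                             node_spacing_um = 40,
                             vessel_brush_px = 3L,
                             ring_um = 15,
                             gap_depth_um = 18,
                             n_shadows = 0L) {
  gt <- as.list(gt)
  check_number(resolution, "resolution", min = 64)
  check_number(field_um, "field_um", min = 1)
  upp <- field_um / resolution
  a_px <- gt$faz_semi_major / upp
  b_px <- gt$faz_semi_minor / upp
  if (is.null(a_px) || is.null(b_px) || b_px <= 0 || a_px < b_px) {
    abort("invalid ground truth: need faz_semi_major >= faz_semi_minor > 0")
  }
  reach_px <- a_px + (if ((gt$n_gaps %||% 0L) > 0L) gap_depth_um / upp else 0)
  if (reach_px > 0.4 * resolution) {
    abort(sprintf(
      "FAZ ellipse (reach %.0f um) exceeds the frame: needs a margin of 10%% of the %.0f um field",
      reach_px * upp, field_um))
  }
  withr::with_seed(
    gt$render_seed %||% 1L,
    render_impl(gt, resolution, upp, a_px, b_px,
                node_spacing_um / upp, vessel_brush_px,
                ring_um / upp, gap_depth_um / upp, n_shadows)
  )
}

render_impl <- function(gt, res, upp, a, b, spacing_px, brush_px,
                        ring_px, gap_depth_px, n_shadows) {
  grid <- pixel_grid(res)
  cx <- (res + 1) / 2
  th <- (gt$faz_orientation %||% 0) * pi / 180
  dx <- grid$X - cx
  dy <- -(grid$Y - cx)                       # y-up
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  rho <- sqrt((xr / a)^2 + (yr / b)^2)       # 1 on the ellipse boundary
  d <- sqrt(dx^2 + dy^2)
  # radial distance beyond the ellipse along each pixel's ray
  radial_out <- ifelse(rho > 1, d * (1 - 1 / rho), 0)

  ## jittered-lattice capillary mesh -------------------------------------
  s <- max(spacing_px, 2)
  ax_ <- seq(-s, res + s, by = s)
  nodes_x <- outer(ax_, rep(1, length(ax_)))
  nodes_y <- outer(rep(1, length(ax_)), ax_)
  jit <- 0.3 * s
  nodes_x <- nodes_x + runif(length(nodes_x), -jit, jit)
  nodes_y <- nodes_y + runif(length(nodes_y), -jit, jit)
  nxg <- length(ax_)

  # snap nodes just outside the arcade onto the ring so no avascular moat
  # can form between the arcade and the first lattice ring
  ndx <- nodes_x - cx
  ndy <- -(nodes_y - cx)
  nxr <- ndx * cos(th) + ndy * sin(th)
  nyr <- -ndx * sin(th) + ndy * cos(th)
  nrho <- sqrt((nxr / a)^2 + (nyr / b)^2)
  nd <- sqrt(ndx^2 + ndy^2)
  n_out <- ifelse(nrho > 1, nd * (1 - 1 / nrho), -1)
  snap <- nrho > 1 & n_out < 1.2 * s
  scale <- (nd / nrho + ring_px * 0.5) / pmax(nd, 1e-9)
  nodes_x[snap] <- cx + ndx[snap] * scale[snap]
  nodes_y[snap] <- cx - ndy[snap] * scale[snap]

  idx <- matrix(seq_along(nodes_x), nxg, nxg)
  e_h <- cbind(as.vector(idx[-nxg, ]), as.vector(idx[-1L, ]))       # along x
  e_v <- cbind(as.vector(idx[, -nxg]), as.vector(idx[, -1L]))       # along y
  edges <- rbind(e_h, e_v)

  # capillary dropout: delete a fraction of edges away from the arcade
  dropout <- gt$dropout_fraction %||% 0
  if (dropout > 0) {
    mx <- (nodes_x[edges[, 1]] + nodes_x[edges[, 2]]) / 2
    my <- (nodes_y[edges[, 1]] + nodes_y[edges[, 2]]) / 2
    mdx <- mx - cx; mdy <- -(my - cx)
    mxr <- mdx * cos(th) + mdy * sin(th)
    myr <- -mdx * sin(th) + mdy * cos(th)
    mrho <- sqrt((mxr / a)^2 + (myr / b)^2)
    md <- sqrt(mdx^2 + mdy^2)
    eligible <- which(mrho > 1 & md * (1 - 1 / mrho) > gap_depth_px + 1.5 * s)
    kill <- eligible[runif(length(eligible)) < dropout]
    if (length(kill) > 0L) edges <- edges[-kill, , drop = FALSE]
  }

  ## rasterise edges at ~1 px steps, then dilate to vessel thickness ------
  x1 <- nodes_x[edges[, 1]]; y1 <- nodes_y[edges[, 1]]
  x2 <- nodes_x[edges[, 2]]; y2 <- nodes_y[edges[, 2]]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  npts <- pmax(2L, ceiling(len))
  ei <- rep.int(seq_along(npts), npts)
  tt <- (sequence(npts) - 1) / (npts[ei] - 1)
  px <- round(x1[ei] + tt * (x2[ei] - x1[ei]))
  py <- round(y1[ei] + tt * (y2[ei] - y1[ei]))
  keep <- px >= 1 & px <= res & py >= 1 & py <= res
  mesh <- matrix(FALSE, res, res)
  mesh[cbind(py[keep], px[keep])] <- TRUE
  if (brush_px >= 3L) {
    mesh <- EBImage::dilate(mesh, EBImage::makeBrush(as.integer(brush_px), "disc")) > 0
  }

  ## assemble vessels: mesh outside the FAZ plus the arcade ring ----------
  ring <- rho > 1 & radial_out <= ring_px
  vessel <- (mesh & rho >= 1) | ring
  vessel[rho < 1] <- FALSE

  ## arcade gaps: erase contiguous sectors so the FAZ grows through them --
  n_gaps <- gt$n_gaps %||% 0L
  if (n_gaps > 0L) {
    phi <- atan2(dy, dx) * 180 / pi                     # (-180, 180]
    centers <- runif(n_gaps, 0, 360) - 180
    half <- (gt$gap_arc %||% 40) / 2
    in_gap <- matrix(FALSE, res, res)
    for (gc in centers) {
      dphi <- abs((phi - gc + 180) %% 360 - 180)
      in_gap <- in_gap | dphi <= half
    }
    vessel[in_gap & rho > 1 & radial_out <= gap_depth_px] <- FALSE
  }

  ## shadow artifacts: circular signal voids outside the perifoveal zone --
  shadow <- matrix(FALSE, res, res)
  if (n_shadows > 0L) {
    for (k in seq_len(n_shadows)) {
      sphi <- runif(1, 0, 2 * pi)
      srad <- runif(1, 0.08, 0.14) * res
      rad_at <- a * b / sqrt((b * cos(sphi - th))^2 + (a * sin(sphi - th))^2)
      sc_d <- rad_at + gap_depth_px + srad + 0.05 * res
      sx <- cx + sc_d * cos(sphi)
      sy <- cx - sc_d * sin(sphi)
      shadow <- shadow | ((grid$X - sx)^2 + (grid$Y - sy)^2 <= srad^2)
    }
  }

  ## bimodal intensities --------------------------------------------------
  img <- matrix(runif(res * res, 0.02, 0.22), res, res)
  nv <- sum(vessel)
  if (nv > 0L) img[vessel] <- runif(nv, 0.55, 0.95)
  if (any(shadow)) img[shadow] <- img[shadow] * 0.25
  faz_angiogram(img, upp, gt$layer %||% "superficial", gt$eye_id %||% "eye")
}
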