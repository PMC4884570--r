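# Strata used for the typical / atypical orientation assignment. The typical
# support is the 15-degree band (inclusive) around the horizontal and
# vertical axes, written on [0, 180): [0,15] u [75,105] u [165,180).
TYPICAL_INTERVALS <- rbind(c(0, 15), c(75, 105), c(165, 180))
ATYPICAL_INTERVALS <- rbind(c(15, 75), c(105, 165))

# Draw one orientation uniformly from the intersection of a stratum (set of
# intervals) with the feasibility band [theta_min, 180 - theta_min] that
# keeps the ellipse construction solvable for the sampled diameters.
draw_orientation <- function(intervals, theta_min) {
  lo <- pmax(intervals[, 1], theta_min)
  hi <- pmin(intervals[, 2], 180 - theta_min)
  len <- pmax(0, hi - lo)
  if (sum(len) <= 0) {
    # Extremely elongated draw: no stratum angle is exactly feasible. Take
    # the stratum angle closest to vertical; the ellipse falls back to its
    # minimum aspect ratio there.
    mids <- (intervals[, 1] + intervals[, 2]) / 2
    k <- which.min(orientation_distance(mids, 90))
    side <- intervals[k, ]
    return(if (side[1] >= 90) side[1] + 0.1 else side[2] - 0.1)
  }
  u <- runif(1L, 0, sum(len))
  k <- which(cumsum(len) >= u)[1L]
  lo[k] + (u - c(0, cumsum(len))[k])
}

# Solve the ellipse semi-axes from a sampled (horizontal extent H, maximum
# extent M, orientation theta): a = M/2 and b chosen so the Feret extent at
# 0 degrees equals H. b is clamped to [min_aspect * a, a].
solve_semi_minor <- function(H, M, theta_deg, min_aspect = 0.25) {
  a <- M / 2
  th <- theta_deg * pi / 180
  r2 <- (H / M)^2
  s2 <- sin(th)^2
  if (s2 < 1e-12) return(a * min_aspect)
  b2 <- a^2 * (r2 - cos(th)^2) / s2
  b <- sqrt(max(b2, 0))
  min(max(b, a * min_aspect), a)
}

#' Sample a synthetic cohort of eyes
#'
#' Draws per-eye FAZ ground truth for every group x layer combination in the
#' parameter set. Per eye, a single standard-normal size factor drives both
#' the horizontal and the maximum Feret diameter (comonotone coupling), so
#' each diameter keeps its configured truncated-normal marginal while the
#' maximum almost surely exceeds the horizontal extent. Orientations are
#' assigned by exact stratification: `round(typical_fraction * n)` eyes per
#' group x layer receive a typical orientation (uniform on the 15-degree
#' bands around 0 and 90 degrees), the rest an atypical one (uniform on the
#' complement), intersected per eye with the band of orientations for which
#' an ellipse with the sampled extents exists. DR eyes receive at least one
#' arcade gap and a capillary-dropout fraction; control eyes get neither.
#' BCVA follows the linear model
#' `bcva = intercept + slope * max_diam_superficial + noise`, clipped to
#' [0, 100] letters.
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per eye per layer: identifiers (`eye_id`,
#'   `group`, `layer`), sampled extents (`h_diam_um`, `max_diam_um`), the
#'   ellipse ground truth (`faz_semi_major`, `faz_semi_minor`,
#'   `faz_orientation`), the assigned stratum (`typical`), lesion parameters
#'   (`n_gaps`, `gap_arc`, `dropout_fraction`), `bcva` and `render_seed`.
#' @examples
#' cohort <- sample_cohort(cohort_params(seed = 1))
#' dplyr::count(cohort, group, layer, typical)
#' @export
sample_cohort <- function(params) {
  if (!inherits(params, "faz_cohort_params")) {
    abort("`params` must be created by cohort_params()")
  }
  withr::with_seed(params$seed, sample_cohort_impl(params))
}

sample_cohort_impl <- function(params) {
  n_by_group <- c(control = params$n_control, dr = params$n_dr)
  eye_ids <- c(sprintf("ctrl_%02d", seq_len(params$n_control)),
               sprintf("dr_%02d", seq_len(params$n_dr)))
  eye_group <- rep(names(n_by_group), n_by_group)
  # one latent size factor per eye, shared across layers
  z_eye <- stats::setNames(rnorm(length(eye_ids)), eye_ids)

  rows <- list()
  counter <- 0L
  for (gi in seq_len(nrow(params$groups))) {
    g <- params$groups[gi, ]
    ids <- eye_ids[eye_group == g$group]
    n <- length(ids)
    z <- z_eye[ids]
    # redraw the shared factor only if it would take a diameter non-positive
    bad <- which(g$mean_h_diam + g$sd_h_diam * z <= 0 |
                   g$mean_max_diam + g$sd_max_diam * z <= 0)
    while (length(bad) > 0L) {
      z[bad] <- rnorm(length(bad))
      bad <- which(g$mean_h_diam + g$sd_h_diam * z <= 0 |
                     g$mean_max_diam + g$sd_max_diam * z <= 0)
    }
    H <- g$mean_h_diam + g$sd_h_diam * z
    M <- pmax(g$mean_max_diam + g$sd_max_diam * z, H)

    n_typ <- round(g$typical_fraction * n)
    typical <- rep(FALSE, n)
    typical[sample.int(n, n_typ)] <- TRUE

    theta <- numeric(n)
    b <- numeric(n)
    for (i in seq_len(n)) {
      min_aspect <- 0.25
      r <- H[i] / M[i]
      cmax2 <- (r^2 - min_aspect^2) / (1 - min_aspect^2)
      theta_min <- if (cmax2 <= 0) 90 else acos(min(sqrt(cmax2), 1)) * 180 / pi
      ivals <- if (typical[i]) TYPICAL_INTERVALS else ATYPICAL_INTERVALS
      theta[i] <- draw_orientation(ivals, theta_min)
      b[i] <- solve_semi_minor(H[i], M[i], theta[i], min_aspect)
    }

    is_dr <- g$group == "dr"
    n_gaps <- if (is_dr) 1L + rpois(n, params$n_gaps_lambda) else rep(0L, n)
    dropout <- if (is_dr) runif(n, params$dropout_range[1], params$dropout_range[2]) else rep(0, n)

    rows[[gi]] <- tibble(
      eye_id = ids,
      group = g$group,
      layer = g$layer,
      h_diam_um = H,
      max_diam_um = M,
      faz_semi_major = M / 2,
      faz_semi_minor = b,
      faz_orientation = fold_angle(theta),
      typical = typical,
      n_gaps = n_gaps,
      gap_arc = ifelse(n_gaps > 0L, params$gap_arc_deg, 0),
      dropout_fraction = dropout,
      render_seed = vapply(seq_len(n), function(i) {
        derive_seed(params$seed, counter + i)
      }, integer(1))
    )
    counter <- counter + n
  }
  out <- dplyr::bind_rows(rows)

  # BCVA per eye from its superficial maximum diameter, replicated across
  # layers so both layers of an eye share one acuity.
  sup <- out[out$layer == "superficial", ]
  noise <- stats::setNames(rnorm(nrow(sup), 0, params$bcva_noise_sd), sup$eye_id)
  bcva_eye <- pmin(pmax(
    params$bcva_intercept + params$bcva_slope * sup$max_diam_um + noise[sup$eye_id],
    0), 100)
  names(bcva_eye) <- sup$eye_id
  out$bcva <- unname(bcva_eye[out$eye_id])
  out
}
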