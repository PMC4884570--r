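# Internal helpers shared across modules.

# Derive a per-eye render seed from the cohort master seed and a running
# counter. Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master_seed, counter) {
  base <- as.numeric(master_seed) %% 19997
  as.integer(base * 100003 + (counter %% 100003))
}

# Truncated-at-zero normal draws: plain Gaussian redrawn while non-positive.
# At the FAZ scales used here (mean several hundred um, sd a few hundred um)
# redraws are rare, so the loop terminates almost immediately.
rtruncnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x <= 0)
    guard <- guard + 1L
    if (guard > 1000L) abort("truncated-normal sampler failed to converge; check mean/sd")
  }
  x
}

#' Fold an angle into the orientation half-circle
#'
#' Orientations of undirected chords live on [0, 180); this folds any angle
#' in degrees into that range.
#'
#' @param theta Angle(s) in degrees.
#' @return Angle(s) in [0, 180).
#' @export
fold_angle <- function(theta) {
  out <- theta %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}

#' Angular distance between two orientations
#'
#' Distance on the half-circle: `orientation_distance(179, 1)` is 2, not
#' 178.
#'
#' @param a,b Orientation(s) in degrees (folded internally).
#' @return Distance(s) in degrees, in [0, 90].
#' @export
orientation_distance <- function(a, b) {
  d <- abs(fold_angle(a) - fold_angle(b))
  pmin(d, 180 - d)
}

# Shoelace area of a closed polygon given as a two-column matrix (x, y).
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < sqrt(.Machine$double.eps)) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g]", name, x, min, max))
  }
  invisible(x)
}
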