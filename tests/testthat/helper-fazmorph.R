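# Shared fixtures: analytic shapes and tiny ground-truth rows, all built in
# code at test time.

# densely sampled ellipse boundary in pixel coordinates (y down)
ellipse_boundary <- function(a, b, theta_deg = 0, cx = 0, cy = 0, n = 2000) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  th <- theta_deg * pi / 180
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(cx + x0 * cos(th) - y0 * sin(th),
        cy - (x0 * sin(th) + y0 * cos(th)))   # flip to y-down
}

# random star-convex blob mask + its (unsmoothed) marching-squares boundary
random_blob_boundary <- function(size = 80, seed = 1) {
  set.seed(seed)
  base <- runif(1, size * 0.15, size * 0.3)
  k <- 2:5
  amp <- runif(length(k), 0, 0.12)
  phs <- runif(length(k), 0, 2 * pi)
  cx <- (size + 1) / 2
  X <- matrix(rep(seq_len(size), each = size), size)
  Y <- matrix(rep(seq_len(size), size), size)
  phi <- atan2(-(Y - cx), X - cx)
  r <- sqrt((X - cx)^2 + (Y - cx)^2)
  rad <- base * (1 + colSums(amp * cos(outer(k, phi, "*") + phs)))
  mask <- (r <= matrix(rad, size, size)) * 1
  cl <- grDevices::contourLines(x = seq_len(size), y = seq_len(size),
                                z = mask, levels = 0.5)
  areas <- vapply(cl, function(ct) {
    fazmorph:::polygon_area(cbind(ct$y, ct$x))
  }, numeric(1))
  ct <- cl[[which.max(areas)]]
  cbind(x = ct$y, y = ct$x)
}

# minimal ground-truth row for direct rendering
make_gt <- function(a = 300, b = 250, theta = 30, n_gaps = 0L, gap_arc = 0,
                    dropout = 0, seed = 5L, layer = "superficial",
                    eye_id = "test_eye") {
  tibble::tibble(
    eye_id = eye_id, group = if (n_gaps > 0) "dr" else "control",
    layer = layer, faz_semi_major = a, faz_semi_minor = b,
    faz_orientation = theta, typical = NA, n_gaps = as.integer(n_gaps),
    gap_arc = gap_arc, dropout_fraction = dropout, render_seed = as.integer(seed),
    bcva = 85)
}

# brute-force maximum pairwise distance (the independent O(n^2) oracle)
brute_force_max <- function(pts) {
  max(stats::dist(pts))
}
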