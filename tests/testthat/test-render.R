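test_that("rendering is deterministic given the render seed", {
  gt <- make_gt(a = 320, b = 240, theta = 40, seed = 17L)
  i1 <- render_angiogram(gt)
  i2 <- render_angiogram(gt)
  expect_identical(i1$pixels, i2$pixels)
  gt2 <- gt; gt2$render_seed <- 18L
  expect_false(identical(render_angiogram(gt2)$pixels, i1$pixels))
})

test_that("a control eye yields a closed, simply connected FAZ off the border", {
  gt <- make_gt(a = 350, b = 260, theta = 75, seed = 3L)
  reg <- extract_faz(render_angiogram(gt))
  res <- nrow(reg$mask)
  expect_false(any(reg$mask[c(1, res), ]) || any(reg$mask[, c(1, res)]))
  # simply connected: no avascular holes inside the component (the inverse
  # of the mask touches the border everywhere outside)
  inv <- (!reg$mask) * 1
  lab <- EBImage::bwlabel(inv)
  border_labels <- unique(c(lab[1, ], lab[res, ], lab[, 1], lab[, res]))
  expect_true(all(unique(as.vector(lab[lab > 0])) %in% border_labels))
})

test_that("a circular FAZ measures its analytic diameter and area", {
  gt <- make_gt(a = 300, b = 300, theta = 0, seed = 9L)
  img <- render_angiogram(gt)
  reg <- extract_faz(img)
  m <- measure_angiogram(img, region = reg)
  expect_lt(abs(m$max_um - 600) / 600, 0.05)
  expect_lt(abs(m$area_um2 - pi * 300^2) / (pi * 300^2), 0.10)
})

test_that("arcade gaps strictly enlarge the avascular component", {
  gt <- make_gt(a = 300, b = 240, theta = 20, seed = 9L)
  gt_gap <- gt; gt_gap$n_gaps <- 2L; gt_gap$gap_arc <- 40
  a0 <- sum(extract_faz(render_angiogram(gt))$mask)
  a2 <- sum(extract_faz(render_angiogram(gt_gap))$mask)
  expect_gt(a2, a0)
})

test_that("an ellipse exceeding the frame margin is rejected", {
  gt <- make_gt(a = 900, b = 700)
  expect_error(render_angiogram(gt), "margin")
  # but fits once the field is widened
  expect_s3_class(render_angiogram(gt, field_um = 3000), "faz_angiogram")
})

test_that("binarisation is threshold-robust on the intensity plateau", {
  gt <- make_gt(a = 280, b = 220, theta = 120, n_gaps = 1L, gap_arc = 30, seed = 21L)
  img <- render_angiogram(gt)
  r1 <- extract_faz(img, vessel_threshold = 0.30)
  r2 <- extract_faz(img, vessel_threshold = 0.50)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$boundary, r2$boundary)
})

test_that("degenerate frames abort with informative errors", {
  # no vessels at all: the avascular region hits the frame border
  empty <- faz_angiogram(matrix(0, 304, 304), 6.579)
  expect_error(extract_faz(empty), "border")
  # solid vessel frame: the centre pixel is not avascular
  solid <- faz_angiogram(matrix(1, 304, 304), 6.579)
  expect_error(extract_faz(solid), "centre|vessel")
})

test_that("shadow artifacts do not disturb the FAZ measurement", {
  gt <- make_gt(a = 300, b = 250, theta = 60, seed = 4L)
  m0 <- measure_angiogram(render_angiogram(gt))
  m1 <- measure_angiogram(render_angiogram(gt, n_shadows = 2L))
  expect_lt(abs(m1$max_um - m0$max_um) / m0$max_um, 0.02)
})

test_that("angiograms round-trip through 8-bit PNG", {
  gt <- make_gt(seed = 2L)
  img <- render_angiogram(gt)
  path <- withr::local_tempfile(fileext = ".png")
  write_angiogram(img, path)
  back <- read_angiogram(path, um_per_pixel = img$um_per_pixel)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)
  # measurements agree despite the 8-bit quantisation
  m1 <- measure_angiogram(img)
  m2 <- measure_angiogram(back)
  expect_equal(m2$max_um, m1$max_um, tolerance = 1e-6)
})
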