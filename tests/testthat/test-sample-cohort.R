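test_that("stratified orientation assignment hits the rounded count exactly", {
  cases <- list(
    list(n_control = 25L, n_dr = 29L),   # reference sizes: 18/25 and 2/29
    list(n_control = 10L, n_dr = 12L),
    list(n_control = 7L, n_dr = 31L)
  )
  for (cs in cases) {
    for (seed in c(1L, 19L, 402L)) {
      p <- cohort_params(n_control = cs$n_control, n_dr = cs$n_dr, seed = seed)
      co <- sample_cohort(p)
      counts <- dplyr::count(co, .data$group, .data$layer,
                             wt = as.integer(.data$typical))
      for (i in seq_len(nrow(p$groups))) {
        g <- p$groups[i, ]
        n <- if (g$group == "control") cs$n_control else cs$n_dr
        got <- counts$n[counts$group == g$group & counts$layer == g$layer]
        expect_identical(got, as.integer(round(g$typical_fraction * n)))
      }
      # the assigned stratum agrees with the classification of the true angle
      expect_identical(classify_angle(co$faz_orientation) == "typical",
                       co$typical)
    }
  }
})

test_that("the same seed reproduces the cohort element-wise", {
  p <- cohort_params(seed = 123L)
  expect_identical(sample_cohort(p), sample_cohort(p))
  expect_false(identical(sample_cohort(cohort_params(seed = 124L)),
                         sample_cohort(p)))
})

test_that("ground-truth invariants hold", {
  co <- sample_cohort(cohort_params(seed = 31L))
  expect_true(all(co$faz_semi_major >= co$faz_semi_minor))
  expect_true(all(co$faz_semi_minor > 0))
  expect_true(all(co$faz_orientation >= 0 & co$faz_orientation < 180))
  expect_true(all(co$max_diam_um >= co$h_diam_um))
  ctrl <- co[co$group == "control", ]
  expect_true(all(ctrl$n_gaps == 0L & ctrl$dropout_fraction == 0))
  dr <- co[co$group == "dr", ]
  expect_true(all(dr$n_gaps >= 1L))
  expect_true(all(co$bcva >= 0 & co$bcva <= 100))
  # both layers of an eye share one acuity
  by_eye <- tapply(co$bcva, co$eye_id, function(v) length(unique(v)))
  expect_true(all(by_eye == 1L))
})

test_that("sampled diameters converge to the configured group means", {
  # large-n check: each cohort mean within 3 standard errors of the target
  for (seed in c(2L, 56L, 91L)) {
    p <- cohort_params(n_control = 1000L, n_dr = 1000L, seed = seed)
    co <- sample_cohort(p)
    for (i in seq_len(nrow(p$groups))) {
      g <- p$groups[i, ]
      d <- co[co$group == g$group & co$layer == g$layer, ]
      se_h <- g$sd_h_diam / sqrt(nrow(d))
      se_m <- g$sd_max_diam / sqrt(nrow(d))
      expect_lt(abs(mean(d$h_diam_um) - g$mean_h_diam), 3 * se_h)
      expect_lt(abs(mean(d$max_diam_um) - g$mean_max_diam), 3 * se_m)
    }
  }
})

test_that("the BCVA model induces a negative rank correlation with FAZ size", {
  rhos <- vapply(1:20, function(s) {
    co <- sample_cohort(cohort_params(seed = 600L + s))
    d <- co[co$layer == "superficial", ]
    spearman_rho(d$max_diam_um, d$bcva)$statistic
  }, numeric(1))
  expect_true(all(rhos < 0))
  expect_gt(abs(mean(rhos)), 0.3)
  expect_lt(abs(mean(rhos)), 0.85)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n_control = 0), "n_control")
  expect_error(cohort_params(n_dr = -3), "n_dr")
  bad <- reference_cohort()[, -3]
  bad$typical_fraction[1] <- 1.4
  expect_error(cohort_params(groups = bad), "typical_fraction")
  bad2 <- reference_cohort()[, -3]
  bad2$sd_h_diam[2] <- 0
  expect_error(cohort_params(groups = bad2), "SD")
  expect_error(sample_cohort(list()), "cohort_params")
})
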