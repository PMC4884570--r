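test_that("Mann-Whitney U: exact small-sample behaviour and invariants", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  # identical multisets give U = n * m / 2
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_u(x, x)$statistic, length(x)^2 / 2)
  # U_x + U_y = n * m for arbitrary data with ties
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:8, sample(3:12, 1), replace = TRUE)
    b <- sample(1:8, sample(3:12, 1), replace = TRUE)
    u1 <- mann_whitney_u(a, b)$statistic
    u2 <- mann_whitney_u(b, a)$statistic
    expect_equal(u1 + u2, length(a) * length(b))
    # invariance under a strictly monotone transform of the pooled data
    expect_equal(mann_whitney_u(exp(a / 3), exp(b / 3))$statistic, u1)
  }
  # large shift: overwhelming evidence
  set.seed(6)
  y <- rnorm(25, 600, 150)
  expect_lt(mann_whitney_u(y + 1000, y)$p_value, 0.001)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Spearman's rho: closed form, extremes and errors", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 6, 4, 10)
  set.seed(8)
  y <- sample(x)
  r <- spearman_rho(x, y)
  d <- rank(x) - rank(y)
  n <- length(x)
  expect_equal(r$statistic, 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  # strictly monotone transforms pin rho at +/-1
  expect_equal(spearman_rho(x, exp(x))$statistic, 1)
  expect_equal(spearman_rho(x, -x^3)$statistic, -1)
  # invariance under monotone transforms of either variable
  expect_equal(spearman_rho(log(x), y)$statistic, r$statistic)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("ICC(2,1) equals the explicit two-way ANOVA oracle", {
  icc_oracle <- function(m) {
    # independent route: aov() mean squares pushed through Shrout-Fleiss 2,1
    n <- nrow(m); k <- ncol(m)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    m <- matrix(sample(0:8, n * k, replace = TRUE) + rnorm(n * k, 0, 0.3), n, k)
    expect_equal(icc_2_1(m)$statistic, icc_oracle(m), tolerance = 1e-10)
  }
  # perfect agreement with subject variance
  m <- cbind(1:6, 1:6)
  expect_equal(icc_2_1(m)$statistic, 1)
  expect_error(icc_2_1(matrix(3, 4, 2)), "degenerate|undefined")
  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(icc_2_1(matrix(1:4, 4, 1)), "raters")
})

test_that("Cohen's kappa matches the hand formula and is symmetric", {
  # agreement table: 30 both-atypical, 18 both-typical, 3 + 3 disagreements
  a <- c(rep("atyp", 30), rep("typ", 18), rep("atyp", 3), rep("typ", 3))
  b <- c(rep("atyp", 30), rep("typ", 18), rep("typ", 3), rep("atyp", 3))
  n <- length(a)
  p_o <- 48 / n
  p_e <- (33 / n) * (33 / n) + (21 / n) * (21 / n)
  r <- cohen_kappa(a, b)
  expect_equal(r$statistic, (p_o - p_e) / (1 - p_e), tolerance = 1e-12)
  expect_equal(cohen_kappa(b, a)$statistic, r$statistic)
  # identical labels: kappa = 1
  expect_equal(cohen_kappa(a, a)$statistic, 1)
  # independent labels drift to zero
  set.seed(12)
  big_a <- sample(c("x", "y"), 4000, replace = TRUE)
  big_b <- sample(c("x", "y"), 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(big_a, big_b)$statistic), 0.06)
  expect_error(cohen_kappa(rep("x", 5), rep("x", 5)), "constant")
  expect_error(cohen_kappa(1:3, 1:4), "equal length")
})

test_that("the Shapiro-Wilk gate is calibrated and powered", {
  set.seed(13)
  # type-I: close to the nominal 5% on normal samples
  rej <- mean(vapply(1:400, function(i) {
    shapiro_wilk_gate(rnorm(100))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  # power: heavy right skew is caught nearly always
  pow <- mean(vapply(1:60, function(i) {
    shapiro_wilk_gate(stats::rexp(100))$p_value < 0.05
  }, logical(1)))
  expect_gt(pow, 0.9)
  expect_error(shapiro_wilk_gate(rep(2, 10)), "variance")
  expect_error(shapiro_wilk_gate(1:2), "3 <= n")
  r <- shapiro_wilk_gate(stats::rexp(50))
  expect_match(r$method_notes, "non-parametric")
})

test_that("Snellen fractions convert to ETDRS letters by the log10 rule", {
  expect_identical(snellen_to_etdrs(1.0), 85L)
  expect_identical(snellen_to_etdrs(0.5), 70L)
  expect_identical(snellen_to_etdrs(0.1), 35L)
  expect_identical(snellen_to_etdrs(c(20 / 20, 20 / 40, 20 / 200)),
                   c(85L, 70L, 35L))
  # clipping at both ends of the letter scale
  expect_identical(snellen_to_etdrs(1e6), 100L)
  expect_identical(snellen_to_etdrs(1e-6), 0L)
  expect_error(snellen_to_etdrs(0), "positive")
  expect_error(snellen_to_etdrs(-0.5), "positive")
})

test_that("the cohort battery returns tidy per-test rows", {
  co <- sample_cohort(cohort_params(seed = 21L))
  m <- tibble::tibble(
    eye_id = co$eye_id, layer = co$layer, group = co$group,
    horizontal_um = co$h_diam_um, vertical_um = co$h_diam_um,
    max_um = co$max_diam_um, perp_um = co$h_diam_um, bcva = co$bcva)
  gt <- cohort_group_tests(m)
  expect_identical(nrow(gt), 8L)      # 2 layers x 4 diameters
  expect_true(all(gt$p_value >= 0 & gt$p_value <= 1))
  expect_true(all(gt$mean_dr > gt$mean_control))
  bc <- bcva_correlations(m)
  expect_identical(nrow(bc), 4L)
  expect_true(all(bc$rho < 0))
})
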