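ref_sup <- matrix(c(27L, 7L, 2L, 18L), 2L,
                  dimnames = list(c("dr", "control"), c("atypical", "typical")))
ref_deep <- matrix(c(25L, 6L, 4L, 19L), 2L,
                   dimnames = list(c("dr", "control"), c("atypical", "typical")))

test_that("contingency tables cross-tabulate classes against groups", {
  classes <- c(rep("atypical", 27), rep("typical", 2),
               rep("atypical", 7), rep("typical", 18))
  labels <- c(rep("dr", 29), rep("control", 25))
  tab <- build_contingency(classes, labels)
  expect_identical(tab, ref_sup)
  # permutation invariance
  set.seed(1)
  perm <- sample(length(classes))
  expect_identical(build_contingency(classes[perm], labels[perm]), tab)
  # all-atypical input leaves the typical column empty
  tab2 <- build_contingency(rep("atypical", 10),
                            rep(c("dr", "control"), 5))
  expect_identical(unname(tab2[, "typical"]), c(0L, 0L))
  expect_error(build_contingency(character(0), character(0)), "empty")
  expect_error(build_contingency("atypical", "dr"), "both groups")
})

test_that("sensitivity and specificity carry exact Clopper-Pearson intervals", {
  d <- sens_spec_ci(ref_sup)
  expect_equal(d$sensitivity, 27 / 29)
  expect_equal(d$specificity, 18 / 25)
  # independent oracle: direct Beta-quantile form of the exact interval
  cp <- function(x, n) c(qbeta(0.025, x, n - x + 1), qbeta(0.975, x + 1, n - x))
  expect_equal(d$sens_ci95, cp(27, 29), tolerance = 1e-12)
  expect_equal(d$spec_ci95, cp(18, 25), tolerance = 1e-12)
  d2 <- sens_spec_ci(ref_deep)
  expect_equal(d2$sens_ci95, cp(25, 29), tolerance = 1e-12)
  expect_equal(d2$spec_ci95, cp(19, 25), tolerance = 1e-12)
  # a perfect classifier reaches the upper bound of 1 on both intervals
  perf <- sens_spec_ci(matrix(c(12L, 0L, 0L, 12L), 2L))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$sens_ci95[2], 1)
  expect_equal(perf$spec_ci95[2], 1)
  expect_error(sens_spec_ci(matrix(c(0L, 3L, 0L, 4L), 2L)), "row sums")
})

test_that("tidy and glance expose the diagnostic result as tibbles", {
  d <- sens_spec_ci(ref_sup)
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$term, c("sensitivity", "specificity"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(d)
  expect_identical(gl$n, sum(ref_sup))
  expect_gt(gl$chi2_stat, 0)
})

test_that("Pearson chi-square matches the hand formula and its scaling law", {
  hand_chi2 <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  expect_equal(pearson_chi2(ref_sup)$statistic, hand_chi2(ref_sup),
               tolerance = 1e-12)
  # identical rows: no association
  eq <- matrix(c(5L, 5L, 7L, 7L), 2L)
  expect_equal(pearson_chi2(eq)$statistic, 0)
  expect_equal(pearson_chi2(eq)$p_value, 1)
  # doubling all counts doubles the statistic and shrinks p
  r1 <- pearson_chi2(ref_deep)
  r2 <- pearson_chi2(2L * ref_deep)
  expect_equal(r2$statistic, 2 * r1$statistic, tolerance = 1e-12)
  expect_lt(r2$p_value, r1$p_value)
  expect_error(pearson_chi2(matrix(c(0L, 0L, 3L, 4L), 2L)), "marginal")
})

test_that("relabelling both factors swaps sensitivity and specificity", {
  swapped <- ref_sup[2:1, 2:1]
  dimnames(swapped) <- dimnames(ref_sup)
  d <- sens_spec_ci(ref_sup)
  ds <- sens_spec_ci(swapped)
  expect_equal(ds$sensitivity, d$specificity)
  expect_equal(ds$specificity, d$sensitivity)
  expect_equal(ds$sens_ci95, d$spec_ci95)
  expect_equal(ds$chi2_stat, d$chi2_stat)
})

test_that("exact intervals are conservative: coverage at n = 29, p = 0.93", {
  set.seed(2026)
  n <- 29L; p <- 0.93
  x <- stats::rbinom(2000L, n, p)
  lo <- qbeta(0.025, x, n - x + 1)
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  coverage <- mean(lo <= p & p <= hi)
  expect_gte(coverage, 0.95)
})
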