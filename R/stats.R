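# The cohort statistics battery: non-parametric group comparison and
# correlation, inter-grader agreement, the normality gate, and the acuity
# unit conversion. Every test returns a one-row "stat result" tibble so
# batteries of tests stack with bind_rows().

stat_result <- function(name, statistic, p_value, n, method_notes) {
  tibble(name = name, statistic = unname(statistic),
         p_value = unname(p_value), n = as.integer(n),
         method_notes = method_notes)
}

#' Mann-Whitney U test between two independent samples
#'
#' Midrank tie handling throughout. For two groups of at most 8
#' observations each without ties the two-sided p-value is exact
#' (enumeration); otherwise the normal approximation with tie correction
#' is used (no continuity correction). The reported statistic is U for the
#' first sample; `U_x + U_y = n * m` always holds.
#'
#' @param x,y Numeric samples (non-empty).
#' @return One-row stat-result tibble (statistic = U of `x`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  small <- length(x) <= 8L && length(y) <= 8L
  exact <- small && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE, alternative = "two.sided"))
  notes <- if (exact) {
    "exact enumeration (both n <= 8, no ties)"
  } else {
    paste0("normal approximation with tie correction, no continuity correction",
           if (small && has_ties) "; exact p unavailable with ties" else "")
  }
  stat_result("mann_whitney_u", wt$statistic, wt$p.value,
              length(x) + length(y), notes)
}

#' Spearman's rank correlation
#'
#' Midrank-based rho with the two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (>= 3 complete pairs); constant
#'   input is an error (rho undefined).
#' @return One-row stat-result tibble (statistic = rho).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("rho undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  stat_result("spearman_rho", rho, p, n,
              "midranks; two-sided p from t approximation on n - 2 df")
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation (Shrout-Fleiss 2,1):
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`, with MSR, MSC
#' and MSE the subject, rater and residual mean squares of the two-way
#' ANOVA decomposition. The p-value is the usual F test of MSR / MSE.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, at least 2 subjects and 2 raters.
#' @return One-row stat-result tibble (statistic = ICC).
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) abort("ICC requires a complete ratings matrix")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) abort("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom) || denom <= 0 || (msr == 0 && mse == 0)) {
    abort("ICC undefined: degenerate zero-variance ratings")
  }
  icc <- (msr - mse) / denom
  p <- if (mse > 0) pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE) else 0
  stat_result("icc_2_1", icc, p, n,
              sprintf("Shrout-Fleiss ICC(2,1), %d raters; F(%d, %d) test", k, n - 1, (n - 1) * (k - 1)))
}

#' Cohen's kappa between two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal products. The p-value is the two-sided large-sample z test of
#' kappa = 0 (Fleiss standard error under the null).
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return One-row stat-result tibble (statistic = kappa).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0L) abort("empty input")
  levels_all <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels_all)
  b <- factor(labels_b, levels_all)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  pi_ <- rowSums(tab); pj_ <- colSums(tab)
  p_e <- sum(pi_ * pj_)
  if (1 - p_e < .Machine$double.eps) {
    abort("kappa undefined: both raters are constant (chance agreement = 1)")
  }
  kap <- (p_o - p_e) / (1 - p_e)
  se0 <- sqrt((p_e + p_e^2 - sum(pi_ * pj_ * (pi_ + pj_))) / (n * (1 - p_e)^2))
  p <- if (se0 > 0) 2 * pnorm(-abs(kap / se0)) else NA_real_
  stat_result("cohen_kappa", kap, p, n,
              "marginal-product expected agreement; two-sided z test of kappa = 0")
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and records the decision the analysis
#' pipeline takes from it: when p < `alpha` the distribution is treated as
#' non-normal and the non-parametric battery is used downstream.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha Gate level (default 0.05).
#' @return One-row stat-result tibble (statistic = W); `method_notes`
#'   records the gate decision.
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) abort("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(x) == 0) abort("zero variance: normality test undefined")
  sw <- shapiro.test(x)
  nonpar <- sw$p.value < alpha
  stat_result("shapiro_wilk", sw$statistic, sw$p.value, n,
              sprintf("gate at alpha = %g -> %s tests", alpha,
                      if (nonpar) "non-parametric" else "parametric"))
}

#' Convert a Snellen fraction to an ETDRS letter score
#'
#' `letters = 85 + 50 * log10(fraction)`, rounded to the nearest integer
#' and clipped to [0, 100]: 20/20 maps to 85 letters, 20/40 to 70, 20/200
#' to 35.
#'
#' @param snellen_fraction Positive ratio(s), e.g. `20/40` written as 0.5.
#' @return Integer ETDRS letter score(s).
#' @examples
#' snellen_to_etdrs(c(1, 0.5, 0.1))
#' @export
snellen_to_etdrs <- function(snellen_fraction) {
  if (any(!is.finite(snellen_fraction)) || any(snellen_fraction <= 0)) {
    abort("`snellen_fraction` must be positive and finite")
  }
  as.integer(pmin(pmax(round(85 + 50 * log10(snellen_fraction)), 0), 100))
}

#' Group-comparison battery over measured diameters
#'
#' For each layer and each diameter column, tests DR against control eyes
#' with the Mann-Whitney U test, after logging the Shapiro-Wilk gate per
#' group.
#'
#' @param measurements Measurement tibble with `group`, `layer` and
#'   diameter columns (from [measure_cohort()]).
#' @param diameters Diameter columns to test.
#' @return Tidy tibble: one row per layer x diameter with the U statistic,
#'   p-value, group medians and the gate decision.
#' @export
cohort_group_tests <- function(measurements,
                               diameters = c("horizontal_um", "vertical_um",
                                             "max_um", "perp_um")) {
  diameters <- intersect(diameters, names(measurements))
  combos <- tidyr::expand_grid(layer = unique(measurements$layer),
                               diameter = diameters)
  purrr::pmap_dfr(combos, function(layer, diameter) {
    d <- measurements[measurements$layer == layer, ]
    x <- d[[diameter]][d$group == "dr"]
    y <- d[[diameter]][d$group == "control"]
    gate_p <- suppressWarnings(c(
      tryCatch(shapiro_wilk_gate(x)$p_value, error = function(e) NA_real_),
      tryCatch(shapiro_wilk_gate(y)$p_value, error = function(e) NA_real_)))
    mw <- mann_whitney_u(x, y)
    tibble(
      layer = layer, diameter = diameter,
      median_dr = median(x), median_control = median(y),
      mean_dr = mean(x), mean_control = mean(y),
      u_statistic = mw$statistic, p_value = mw$p_value,
      nonnormal = any(gate_p < 0.05, na.rm = TRUE)
    )
  })
}

#' Correlation of FAZ diameters with visual acuity
#'
#' Spearman correlations of the maximum and perpendicular diameters with
#' BCVA per layer, with pairwise deletion of missing acuities.
#'
#' @param measurements Measurement tibble with `bcva` and diameter columns.
#' @param diameters Diameter columns to correlate with `bcva`.
#' @return Tidy tibble: one row per layer x diameter with rho, p and n.
#' @export
bcva_correlations <- function(measurements,
                              diameters = c("max_um", "perp_um")) {
  diameters <- intersect(diameters, names(measurements))
  combos <- tidyr::expand_grid(layer = unique(measurements$layer),
                               diameter = diameters)
  purrr::pmap_dfr(combos, function(layer, diameter) {
    d <- measurements[measurements$layer == layer, ]
    sr <- spearman_rho(d[[diameter]], d$bcva)
    tibble(layer = layer, diameter = diameter,
           rho = sr$statistic, p_value = sr$p_value, n = sr$n)
  })
}
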