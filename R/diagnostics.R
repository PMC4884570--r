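# The angle-typicality rule as a diagnostic test for diabetic retinopathy.
# An atypical maximum-diameter orientation is the positive test result.

#' Cross-tabulate angle classes against disease labels
#'
#' @param classes Character/factor vector of `"typical"` / `"atypical"`.
#' @param labels Character/factor vector of `"control"` / `"dr"`, same
#'   length; both groups must be present.
#' @return A 2 x 2 integer matrix, rows `dr`/`control`, columns
#'   `atypical`/`typical`.
#' @examples
#' build_contingency(c("atypical", "typical", "atypical"),
#'                   c("dr", "control", "control"))
#' @export
build_contingency <- function(classes, labels) {
  if (length(classes) == 0L) abort("empty input")
  if (length(classes) != length(labels)) {
    abort("`classes` and `labels` must have the same length")
  }
  bad <- setdiff(unique(classes), c("typical", "atypical"))
  if (length(bad) > 0L) abort("`classes` must be 'typical' or 'atypical'")
  bad <- setdiff(unique(labels), c("control", "dr"))
  if (length(bad) > 0L) abort("`labels` must be 'control' or 'dr'")
  if (length(unique(labels)) < 2L) {
    abort("both groups must be present to evaluate sensitivity and specificity")
  }
  tab <- table(factor(labels, c("dr", "control")),
               factor(classes, c("atypical", "typical")))
  m <- matrix(as.integer(tab), 2L, 2L,
              dimnames = list(c("dr", "control"), c("atypical", "typical")))
  m
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Treats "atypical" as the positive test for DR: sensitivity is the
#' atypical fraction among DR eyes, specificity the typical fraction among
#' controls. Confidence intervals are exact Clopper-Pearson binomial
#' intervals; the association is additionally tested with Pearson's
#' chi-square (no continuity correction by default, see [pearson_chi2()]).
#'
#' @param table 2 x 2 count matrix as from [build_contingency()]: rows
#'   `dr`/`control`, columns `atypical`/`typical`; both row sums > 0.
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `faz_diagnostics`; see [tidy.faz_diagnostics()].
#' @examples
#' tab <- matrix(c(27L, 7L, 2L, 18L), 2,
#'               dimnames = list(c("dr", "control"), c("atypical", "typical")))
#' sens_spec_ci(tab)
#' @export
sens_spec_ci <- function(table, confidence = 0.95) {
  table <- validate_table(table)
  check_number(confidence, "confidence", min = 0.5, max = 0.9999)
  n_dr <- sum(table[1, ])
  n_ctrl <- sum(table[2, ])
  if (n_dr == 0L || n_ctrl == 0L) abort("both row sums must be > 0")
  sens_test <- binom.test(table[1, 1], n_dr, conf.level = confidence)
  spec_test <- binom.test(table[2, 2], n_ctrl, conf.level = confidence)
  chi <- tryCatch(pearson_chi2(table), error = function(e) NULL)
  structure(
    list(
      table = table,
      confidence = confidence,
      sensitivity = table[1, 1] / n_dr,
      specificity = table[2, 2] / n_ctrl,
      sens_ci95 = as.numeric(sens_test$conf.int),
      spec_ci95 = as.numeric(spec_test$conf.int),
      chi2_stat = if (is.null(chi)) NA_real_ else chi$statistic,
      chi2_p = if (is.null(chi)) NA_real_ else chi$p_value
    ),
    class = "faz_diagnostics"
  )
}

validate_table <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("`table` must be 2 x 2")
  if (any(table < 0)) abort("counts must be non-negative")
  if (is.null(dimnames(table))) {
    dimnames(table) <- list(c("dr", "control"), c("atypical", "typical"))
  }
  table
}

#' @export
print.faz_diagnostics <- function(x, ...) {
  cat("<faz_diagnostics> atypical maximum-FAZ-diameter angle as test for DR\n")
  print(x$table)
  cat(sprintf("sensitivity %.2f%% (%.0f%% CI %.2f-%.2f)\n",
              100 * x$sensitivity, 100 * x$confidence,
              100 * x$sens_ci95[1], 100 * x$sens_ci95[2]))
  cat(sprintf("specificity %.2f%% (%.0f%% CI %.2f-%.2f)\n",
              100 * x$specificity, 100 * x$confidence,
              100 * x$spec_ci95[1], 100 * x$spec_ci95[2]))
  if (is.finite(x$chi2_stat)) {
    cat(sprintf("Pearson chi-square %.3f, p = %.4g\n", x$chi2_stat, x$chi2_p))
  }
  invisible(x)
}

#' Pearson's chi-square test on a 2 x 2 table
#'
#' Plain Pearson statistic without continuity correction by default (the
#' Yates correction is available via `correct = TRUE`), with the p-value
#' from the chi-square distribution with 1 degree of freedom.
#'
#' @param table 2 x 2 count matrix; all row and column sums must be > 0.
#' @param correct Apply the Yates continuity correction?
#' @return One-row tibble: `name`, `statistic`, `p_value`, `n`,
#'   `method_notes`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  table <- validate_table(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all marginals must be > 0")
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  tibble(
    name = "pearson_chi2",
    statistic = unname(ct$statistic),
    p_value = unname(ct$p.value),
    n = sum(table),
    method_notes = paste0("Pearson chi-square, 1 df, ",
                          if (correct) "Yates-corrected" else "no continuity correction")
  )
}

#' Tidy a diagnostic result
#'
#' @param x A `faz_diagnostics` object.
#' @param ... Unused.
#' @return A tibble with one row per estimate (sensitivity, specificity):
#'   `term`, `estimate`, `conf.low`, `conf.high`, `x`, `n`.
#' @export
tidy.faz_diagnostics <- function(x, ...) {
  successes <- c(x$table[1, 1], x$table[2, 2])
  totals <- c(sum(x$table[1, ]), sum(x$table[2, ]))
  tibble(
    term = c("sensitivity", "specificity"),
    estimate = c(x$sensitivity, x$specificity),
    conf.low = c(x$sens_ci95[1], x$spec_ci95[1]),
    conf.high = c(x$sens_ci95[2], x$spec_ci95[2]),
    x = successes,
    n = totals
  )
}

#' Glance at a diagnostic result
#'
#' @param x A `faz_diagnostics` object.
#' @param ... Unused.
#' @return One-row tibble with the chi-square association test and totals.
#' @export
glance.faz_diagnostics <- function(x, ...) {
  tibble(
    n = sum(x$table),
    chi2_stat = x$chi2_stat,
    chi2_p = x$chi2_p,
    confidence = x$confidence
  )
}
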