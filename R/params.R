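#' Reference cohort summary values
#'
#' Group-level summary statistics of the reference OCT-A cohort that the
#' synthetic generator emulates by default: 25 healthy control eyes and 29
#' eyes with diabetic retinopathy (DR), imaged at the superficial and deep
#' vascular layers. Diameter summaries are mean +/- SD in micrometers of the
#' horizontal and maximum FAZ Feret diameters; `typical_fraction` is the
#' proportion of eyes whose maximum-diameter orientation fell within 15
#' degrees of the horizontal or vertical axis.
#'
#' @return A tibble with one row per group x layer.
#' @export
reference_cohort <- function() {
  tibble(
    group = rep(c("control", "dr"), each = 2L),
    layer = rep(c("superficial", "deep"), 2L),
    n_eyes = c(25L, 25L, 29L, 29L),
    mean_h_diam = c(573, 659, 753, 1009),
    sd_h_diam = c(177, 194, 272, 342),
    mean_max_diam = c(661, 731, 953, 1227),
    sd_max_diam = c(171, 189, 393, 484),
    typical_fraction = c(18 / 25, 19 / 25, 2 / 29, 4 / 29)
  )
}

#' Construct cohort-generator parameters
#'
#' Bundles everything [sample_cohort()] needs: group sizes, per group x layer
#' diameter distributions, stratified typical-orientation fractions, the
#' linear BCVA model, and the master seed. Defaults reproduce the reference
#' cohort returned by [reference_cohort()] (25 control / 29 DR eyes), with a
#' BCVA model calibrated so that group mean acuities land near 84 (control)
#' and 75 (DR) ETDRS letters.
#'
#' @param n_control,n_dr Number of eyes per group (>= 1).
#' @param groups Tibble with columns `group`, `layer`, `mean_h_diam`,
#'   `sd_h_diam`, `mean_max_diam`, `sd_max_diam`, `typical_fraction`; one row
#'   per group x layer. Diameters in micrometers; SDs > 0; fractions in
#'   [0, 1].
#' @param bcva_intercept Intercept of the BCVA model (ETDRS letters).
#' @param bcva_slope Letters per micrometer of superficial maximum FAZ
#'   diameter (<= 0: a larger FAZ predicts poorer acuity).
#' @param bcva_noise_sd Residual SD of the BCVA model (letters, >= 0).
#' @param n_gaps_lambda Poisson rate for extra arcade gaps in DR eyes (each
#'   DR eye gets 1 + Poisson(`n_gaps_lambda`) gaps).
#' @param gap_arc_deg Angular extent of each arcade gap (degrees).
#' @param dropout_range Range of the capillary-dropout fraction outside the
#'   arcade for DR eyes (uniform draw).
#' @param seed Master seed; every draw in [sample_cohort()] derives from it.
#' @return A list of class `faz_cohort_params`.
#' @examples
#' p <- cohort_params(seed = 7)
#' cohort <- sample_cohort(p)
#' @export
cohort_params <- function(n_control = 25L,
                          n_dr = 29L,
                          groups = reference_cohort()[, -3L],
                          bcva_intercept = 103.8,
                          bcva_slope = -0.0305,
                          bcva_noise_sd = 12,
                          n_gaps_lambda = 1,
                          gap_arc_deg = 40,
                          dropout_range = c(0.15, 0.35),
                          seed = 1L) {
  check_number(n_control, "n_control", min = 1)
  check_number(n_dr, "n_dr", min = 1)
  check_number(bcva_intercept, "bcva_intercept")
  check_number(bcva_slope, "bcva_slope", max = 0)
  check_number(bcva_noise_sd, "bcva_noise_sd", min = 0)
  check_number(n_gaps_lambda, "n_gaps_lambda", min = 0)
  check_number(gap_arc_deg, "gap_arc_deg", min = 1, max = 120)
  check_number(seed, "seed")
  groups <- as_tibble(groups)
  needed <- c("group", "layer", "mean_h_diam", "sd_h_diam",
              "mean_max_diam", "sd_max_diam", "typical_fraction")
  missing_cols <- setdiff(needed, names(groups))
  if (length(missing_cols) > 0L) {
    abort(paste0("`groups` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(groups$sd_h_diam <= 0) || any(groups$sd_max_diam <= 0)) {
    abort("all diameter SDs must be > 0")
  }
  if (any(groups$typical_fraction < 0 | groups$typical_fraction > 1)) {
    abort("`typical_fraction` must lie in [0, 1]")
  }
  if (any(groups$mean_h_diam <= 0) || any(groups$mean_max_diam <= 0)) {
    abort("mean diameters must be > 0")
  }
  structure(
    list(
      n_control = as.integer(n_control),
      n_dr = as.integer(n_dr),
      groups = groups[needed],
      bcva_intercept = bcva_intercept,
      bcva_slope = bcva_slope,
      bcva_noise_sd = bcva_noise_sd,
      n_gaps_lambda = n_gaps_lambda,
      gap_arc_deg = gap_arc_deg,
      dropout_range = dropout_range,
      seed = as.integer(seed)
    ),
    class = "faz_cohort_params"
  )
}

#' @export
print.faz_cohort_params <- function(x, ...) {
  cat(sprintf("<faz_cohort_params> %d control + %d DR eyes, seed %d\n",
              x$n_control, x$n_dr, x$seed))
  print(x$groups)
  invisible(x)
}
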