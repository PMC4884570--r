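# fazmorph

Morphometry of the foveal avascular zone (FAZ) on en-face OCT-angiography
frames, and the orientation of its maximum diameter as a screening marker
for diabetic retinopathy (DR).

On OCT-A, the healthy FAZ is a closed, axis-aligned oval bounded by an
intact ring of perifoveal capillaries, so the orientation of its longest
chord lies near the horizontal or vertical image axis ("typical": within
±15° of either axis). In DR the arcades break up, the FAZ enlarges and
its longest chord rotates away from the axes ("atypical"). `fazmorph` is
aimed at readers and implementers of quantitative OCT-A studies: it turns
that observation into a deterministic, testable pipeline, exercised
entirely on synthetic angiograms whose ground truth reproduces the group
statistics of a reference cohort of 25 healthy and 29 DR eyes.

The package provides, as tidyverse-style functions over data frames:

- **Synthetic cohorts and angiograms** — `cohort_params()`,
  `sample_cohort()`, `render_angiogram()`: FAZ ellipses with truncated
  normal diameter marginals, exactly stratified typical/atypical
  orientations, arcade gaps and capillary dropout for DR eyes, a linear
  BCVA (visual acuity) model, and a jittered-lattice capillary renderer
  with bimodal intensities. Fully reproducible from one master seed.
- **Morphometry** — `extract_faz()`, `max_diameter()`,
  `directional_diameter()`, `classify_angle()`, `measure_angiogram()`,
  `measure_cohort()`: the avascular component containing the frame
  centre, traced with a sub-pixel marching-squares boundary; all
  diameters are Feret extents; the maximum Feret diameter is computed by
  rotating calipers on the convex hull (`d_max = max_{p,q} |p - q|`,
  reported with its orientation in `[0°, 180°)`).
- **Diagnostics** — `build_contingency()`, `sens_spec_ci()`,
  `pearson_chi2()`: the 2×2 table of angle class against group, with
  exact Clopper–Pearson 95% intervals for sensitivity and specificity
  and Pearson's chi-square; `tidy()`/`glance()` methods included.
- **Cohort statistics** — `mann_whitney_u()`, `spearman_rho()`,
  `icc_2_1()` (Shrout–Fleiss two-way random, single measure, absolute
  agreement), `cohen_kappa()`, `shapiro_wilk_gate()`,
  `snellen_to_etdrs()` (`letters = 85 + 50·log10(fraction)`), plus the
  batteries `cohort_group_tests()` and `bcva_correlations()` and the
  grader-noise simulator `simulate_graders()`.
- **Orchestration** — `faz_config()` and `run_faz_pipeline()` run
  simulate → render → measure → diagnose → stats in one reproducible
  call and can write a CSV/JSON/markdown report bundle.

## Worked example

```r
library(fazmorph)

cohort <- sample_cohort(cohort_params(seed = 1))       # 54 eyes x 2 layers
gt <- cohort[cohort$eye_id == "dr_03" & cohort$layer == "superficial", ]
measure_angiogram(render_angiogram(gt))
#> # A tibble: 1 x 9
#>   eye_id layer       horizontal_um vertical_um max_um perp_um angle_deg angle_class area_um2
#> 1 dr_03  superficial          369.        363.   384.    351.      150.  atypical    100767.
```

One diabetic eye: a 384 µm maximum diameter oriented at 150° — more than
15° from both axes, hence `atypical`. Measuring the whole superficial
layer and evaluating the angle rule as a screening test:

```r
m <- measure_cohort(cohort[cohort$layer == "superficial", ])
sens_spec_ci(build_contingency(m$angle_class, m$group))
#> <faz_diagnostics> atypical maximum-FAZ-diameter angle as test for DR
#>         atypical typical
#> dr            24       5
#> control        7      18
#> sensitivity 82.76% (95% CI 64.23-94.15)
#> specificity 72.00% (95% CI 50.61-87.93)
#> Pearson chi-square 16.464, p = 4.957e-05
```

24 of 29 DR eyes test positive (atypical) and 18 of 25 controls test
negative, i.e. this seed reproduces the reference specificity (72%)
exactly and loses a little sensitivity to measurement noise near the
±15° class boundary. The FAZ-enlargement contrast comes out of the same
measurements:

```r
cohort_group_tests(m, diameters = c("horizontal_um", "max_um"))
#>         layer      diameter median_dr median_control mean_dr mean_control u_statistic  p_value
#> 1 superficial horizontal_um     749.6          644.2   760.3        601.6         532 3.28e-03
#> 2 superficial        max_um     941.7          726.3   959.6        688.3         587 9.84e-05
```

DR means of ~760 µm (horizontal) and ~960 µm (maximum) against ~600 and
~690 µm in controls, both Mann–Whitney significant — the configured group
separation, recovered through rendering and measurement.

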