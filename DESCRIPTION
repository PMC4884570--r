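Package: fazmorph
Title: Foveal Avascular Zone Morphometry for En-Face OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the foveal avascular zone (FAZ) on en-face
    optical coherence tomography angiography (OCT-A) frames and to evaluate
    the orientation of its maximum Feret diameter as a screening marker for
    diabetic retinopathy. Includes a synthetic angiogram generator that
    renders perifoveal capillary networks with configurable FAZ geometry,
    arcade gaps and capillary dropout; deterministic Feret-diameter
    morphometry on sub-pixel region boundaries (rotating calipers on the
    convex hull); an angle-typicality diagnostic with exact Clopper-Pearson
    confidence intervals; and the accompanying cohort statistics
    (Mann-Whitney, Spearman, ICC(2,1), Cohen's kappa, Shapiro-Wilk gate,
    Snellen to ETDRS conversion). All user-facing functions take and return
    tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
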