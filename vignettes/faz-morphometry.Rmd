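---
title: "FAZ morphometry on synthetic OCT angiograms: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAZ morphometry on synthetic OCT angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fazmorph)
```

## The problem

The foveal avascular zone (FAZ) is the capillary-free region at the centre
of the macula, bounded by a ring of perifoveal capillaries. On en-face OCT
angiography (OCT-A) frames the FAZ of a healthy eye appears as a closed,
vertically or horizontally oval dark region. In diabetic retinopathy (DR)
the surrounding arcades lose integrity: gaps and capillary dropout enlarge
the FAZ and break its axial symmetry, so the orientation of its longest
chord drifts away from the image axes.

`fazmorph` implements this observation as a reproducible measurement
pipeline with three parts:

1. a **synthetic angiogram generator** whose ground truth follows the group
   statistics of a reference clinical cohort (25 healthy control eyes, 29
   DR eyes, imaged at a superficial and a deep vascular layer);
2. **deterministic FAZ morphometry**: the five diameters and the
   orientation of the maximum diameter, replacing a manual line-tool
   protocol with Feret geometry on a sub-pixel region boundary;
3. the **diagnostic evaluation and statistics battery**: the
   typical/atypical orientation rule as a screening test with exact
   binomial confidence intervals, plus the non-parametric group
   comparisons, acuity correlations and inter-grader agreement statistics.

## Measurement definitions

All diameters are **Feret extents**: the width of the projection of the
region boundary onto a unit vector at a given orientation. The maximum FAZ
diameter is the maximum Feret diameter — the greatest distance between any
two boundary points — computed on the convex hull of the boundary by
rotating calipers. The horizontal and vertical diameters are the extents at
0 and 90 degrees, and the "diameter at 90 degrees to the maximum" is the
extent perpendicular to the maximum chord. Feret extents are well defined
for the concave, gap-broken FAZ shapes of DR eyes and coincide with the
intuitive "longest line" of a manual grader for the maximum diameter.
A documented alternative reading — a perpendicular chord through the
maximum chord's midpoint — is not used: it is ill-defined for concave
regions.

Orientations are reported in degrees in `[0, 180)`, with 0 at the image
horizontal and counterclockwise positive. Because pixel coordinates have
the y axis pointing down, all angle computations internally flip the y
axis; the convention is pinned by tests (a chord from bottom-left to
top-right has an angle near 45 degrees, and rotating the frame by a
quarter turn shifts every orientation by 90 degrees while swapping the
horizontal and vertical extents).

An orientation is **typical** when it lies within 15 degrees of either
image axis, with the boundary inclusive: 15, 75, 105 and 165 degrees are
typical. The inclusive choice is a documented convention; the clinical
rule is stated as "0 (+/-15) or 90 (+/-15) degrees" without specifying
boundary handling. Among chords of numerically equal length the smallest
folded angle wins, which makes results on symmetric regions (such as a
square, whose two diagonals tie) deterministic.

Pixel lengths convert to micrometers through the per-image scale; the
default 6.579 um/px corresponds to a 2 x 2 mm frame sampled with 304 x 304
A-scans (304 x 6.579 um = 2.000 mm).

## The synthetic cohort model

The generator's defaults reproduce the reference cohort summaries exposed
by `reference_cohort()`: per group and layer, the mean and SD of the
horizontal and maximum diameters, and the fraction of eyes with a typical
maximum-diameter orientation (18/25 and 19/25 in controls, 2/29 and 4/29
in DR for the superficial and deep layer respectively).

```{r}
reference_cohort()
```

Per eye, the FAZ ground truth is an ellipse constructed from a sampled
pair (horizontal extent `H`, maximum extent `M`) and an orientation:

- **Marginals.** `H` and `M` follow normal distributions truncated at
  zero with the configured means and SDs. At these means the truncation
  point lies 2.5-2.8 SDs below the mean, so the induced upward bias is
  small (about 2 um for the superficial control horizontal diameter and
  about 8 um for the deep DR maximum); it is documented rather than
  corrected.
- **Coupling.** A single standard-normal size factor per eye drives both
  diameters and both layers (comonotone coupling). This preserves each
  configured marginal exactly while making `M >= H` hold almost surely
  (the quantile curves of the configured pairs essentially never cross),
  and it reflects the biological fact that a large FAZ is large in every
  direction. In the rare draws where `M < H`, `M` is raised to `H`; the
  induced bias is below 0.5%.
- **Orientation.** Typicality is imposed by exact stratification:
  `round(typical_fraction * n)` eyes per group and layer draw their
  orientation uniformly from the typical bands, the rest uniformly from
  the complement, so the reference proportions are reproduced exactly at
  the reference group sizes in every seed. An emergent continuous
  orientation distribution could only approximate 2/29 at n = 29. Within
  its stratum each eye's orientation is restricted to the band for which
  an ellipse with extents `(H, M)` exists (the horizontal extent of an
  ellipse with semi-axes `a >= b` at orientation `theta` is
  `2 * sqrt(a^2 cos^2 theta + b^2 sin^2 theta)`, which cannot fall below
  `2a |cos theta|`); the semi-minor axis is then solved from `H`, `M` and
  `theta`, with the aspect ratio floored at 0.25.
- **Lesions.** DR eyes receive `1 + Poisson(1)` arcade gaps of 40 degrees
  each and a capillary-dropout fraction drawn from U(0.15, 0.35); control
  eyes receive neither. The orientation distribution of atypical eyes and
  all lesion parameters are inventions of this module — the reference
  study describes no image model — and are configurable.
- **Acuity.** BCVA follows
  `letters = 103.8 - 0.0305 * max_superficial + N(0, 12)`, clipped to
  [0, 100]. Slope and intercept are chosen so the group mean acuities
  land near the reference values (about 84 letters in controls, 75 in
  DR), and the noise SD so the rank correlation between FAZ size and
  acuity has magnitude near 0.6. The reference study reports conflicting
  correlation coefficients (text and figure values differ, and the
  reported positive sign contradicts the stated direction "larger FAZ,
  poorer acuity"), so only the magnitude and the negative sign chosen
  here are exercised, as a configurable band rather than a point target.
  Snellen fractions convert to letters via `85 + 50 log10(fraction)`.

One master seed drives everything; per-eye render seeds derive from it by
a fixed counter scheme, so cohorts are reproducible element-wise and
individual eyes re-render identically in isolation.

## The renderer

A frame is a square grayscale matrix (default 304 x 304) in `[0, 1]`:

- the **FAZ interior** (the ground-truth ellipse) carries no vessel
  signal;
- the **perifoveal arcade** is a ring of radial thickness 15 um drawn
  outward from the ellipse boundary, so the avascular interior keeps
  exactly the ground-truth extents;
- the **capillary mesh** is a jittered square lattice (40 um spacing,
  vessel thickness 1-3 px) filling the rest of the frame; lattice nodes
  just outside the arcade are snapped onto it so no spurious avascular
  moat can form between ring and mesh;
- **gaps** erase all vessels in `n_gaps` angular sectors to a depth of
  18 um beyond the ellipse: the avascular component grows through the gap
  into a shallow pocket bounded by the surviving mesh. The depth is
  deliberately just past the ring thickness: gaps visibly break the
  arcade and strictly enlarge the avascular *area* while inflating the
  Feret *extents* by only ~1% at cohort level, because the sampled `H`
  and `M` already describe the enlarged diabetic FAZ;
- **dropout** deletes the configured fraction of mesh edges away from the
  arcade; **shadow artifacts** (optional) multiply the signal in circular
  patches placed outside the perifoveal zone by 0.25;
- intensities are **bimodal by construction**: background in
  [0.02, 0.22], vessels in [0.55, 0.95]. Binarisation is therefore
  threshold-robust: every threshold on the plateau (0.25, 0.5] yields the
  identical vessel mask, mirroring the fact that graders were free to
  choose their own binarisation.

What the generator does *not* emulate: the de-correlation physics of the
instrument's flow signal, projection artifacts between layers, motion
artifacts, vessel calibre hierarchy and flow directionality, or real
capillary topology. Passing tests therefore certify the measurement
geometry and the statistical pipeline, not performance on patient images.

## Extraction and its numerical choices

`extract_faz()` binarises at the threshold (default 0.35), morphologically
closes the vessel mask with a 2 px disc, and takes the avascular
4-connected component containing the frame centre. The closing radius
bridges sub-capillary rendering noise (mesh lacunae are ~4 px) but is an
order of magnitude smaller than a rendered arcade gap (~30 px of arc), so
true gaps survive. Error conditions are explicit: a vessel on the centre
pixel (off-centre fixation), a component touching the frame border
(region not fully imaged — an all-background frame ends up here too), or
a component covering more than half the frame (degenerate mask).

The boundary is traced sub-pixel: the component mask is Gaussian-smoothed
(sigma 3 px) and contoured at level 0.5 by marching squares. Smoothing
suppresses the half-pixel staircase of the binary mask, whose longest
flat runs sit exactly at the Feret-extremal tangent points; sigma 3 was
chosen because it minimises the orientation noise of the maximum chord
(median error ~1.4 degrees on reference-sized control eyes, against ~2.8
at sigma 1.2) while the curvature-induced shrinkage stays below 0.5% of
the diameter. Diameters of gap-free eyes are recovered with a median
relative error well under the 5% discretisation budget, and a rendered
300 um-radius circular FAZ measures within 5% of its analytic 600 um
diameter and 10% of its analytic area.

Eyes whose FAZ cannot be extracted are excluded with a warning and
counted, mirroring how unmeasurable frames are handled in practice. For
deep-layer DR eyes the sampled maximum diameter can exceed what a 2 mm
frame can hold with the required 10% margin; `measure_cohort()` then
widens the imaged field for that eye (the pixel scale is per-image
metadata, as in the vendor formats, where both 2 and 3 mm protocols
exist). The alternative — truncating the cohort at the frame size — would
bias the deep DR mean by several percent.

## Diagnostics and statistics conventions

The screening rule treats an atypical orientation as a positive test for
DR. `sens_spec_ci()` reports sensitivity and specificity with exact
Clopper-Pearson intervals (Beta-quantile form, cross-checked in the tests
against `binom.test()`), and Pearson's chi-square without continuity
correction ("Pearson's chi-square" is the stated method; Yates is
available as an option). The published reference bounds differ from exact
Clopper-Pearson values by up to 0.2 percentage points (consistent with a
low-precision implementation in whatever tool produced them); this
package reports the exact values.

The battery mirrors the reference analysis deliberately, including its
limitations:

- eyes are treated as independent observations, ignoring the correlation
  between two eyes of one patient;
- Mann-Whitney U uses midranks, exact enumeration when both groups have
  at most 8 observations and no ties, and the tie-corrected normal
  approximation otherwise (no continuity correction) — with ties in a
  small sample the exact distribution is unavailable and the
  approximation is used and noted;
- Spearman's rho uses midranks with the two-sided t approximation;
- ICC(2,1) is the Shrout-Fleiss two-way random-effects single-measure
  absolute-agreement coefficient computed from the explicit ANOVA mean
  squares (no suitable implementation ships with the environment's
  packages, and the formula is four lines);
- Cohen's kappa uses marginal-product chance agreement with the Fleiss
  null standard error;
- the Shapiro-Wilk gate (p < 0.05 in any group selects the
  non-parametric battery) is logged with every run;
- no multiple-testing correction is applied, matching the reference
  analysis; per-test p-values are reported as such.

Grader noise defaults (150 um diameter SD, 5 degree angle SD) were
calibrated by simulation so two graders over a 54-eye cohort produce an
ICC(2,1) inside [0.7, 0.95] — the band containing the reference
reliability of 0.857 — and an angle-class kappa near 0.8-0.9.

## Known limitations

- **Orientation noise near the class boundary.** The maximum-chord
  orientation of a nearly axis-symmetric region is intrinsically
  ill-conditioned: chord length varies only quadratically with angle, so
  ~0.05 px of residual boundary noise translates into several degrees of
  orientation noise for eyes with axis ratios near 0.85. Eyes drawn
  within a few degrees of the 15-degree class boundary can therefore flip
  class after rendering and measurement. At the reference control
  parameters this depresses the *measured* typical fraction by 3-5
  percentage points relative to the stratified ground truth (e.g. ~68%
  measured against 72% assigned), and the measured per-seed typical
  count matches the stratified count only in a minority of seeds. The
  stratified assignment itself is exact in every seed; the gap between
  assigned and measured typicality is a faithful model of why two human
  graders disagreed on a handful of eyes.
- **Cohort-mean recovery is limited by sampling noise.** With 29 eyes and
  10 seeds the standard error of a DR cohort mean is ~1-2% of the mean;
  end-to-end recovery checks at the 3% level therefore test bias and
  noise together, with render-side bias held near +1% (gap pockets) and
  -0.3% (boundary smoothing).
- The renderer's capillary model is schematic (see above); vessel-density
  or perfusion metrics should not be computed from these frames.

## Problem sizes used by the test suite

The shipped tests run the full render-measure loop on 10 seeds of the
54-eye, two-layer reference cohort for parameter recovery, 100 sampled
cohorts for the Mann-Whitney power check (rejection in at least 80% of
seeds for the superficial horizontal contrast), 250 random point clouds
and 200 rasterised blob masks for the rotating-calipers/brute-force
equivalence, and 2000 simulated binomials for the exact-interval coverage
check. `scripts/acceptance.R` re-renders 830 eyes across 10 seeds.
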