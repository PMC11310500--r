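---
title: "Methods: segmentation metrics and knowledge-based contour QA"
author: "contourQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation metrics and knowledge-based contour QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourQA)
```

## Scope and model

`contourQA` evaluates automatic organ segmentations on CT in two regimes:

* **With ground truth**: a test mask is scored against a clinician-approved
  mask with six volumetric overlap metrics and seven surface-distance
  metrics (all in mm).
* **Without ground truth**: the Hounsfield-unit (HU) distribution inside a
  new contour is compared, via a kernel density estimate (KDE), against a
  per-organ baseline learned from previously approved contours. The working
  assumption is that a correctly placed organ contour encloses a
  characteristic tissue-intensity distribution, largely invariant to organ
  size and patient age, whereas misplaced or mis-shapen contours leak in
  surrounding tissue with a different HU profile.

All volumes and masks live on regular 3-D voxel grids with anisotropic
spacing. No resampling is ever performed: operations on mask pairs require
identical grids (shape, spacing, origin within 1e-6 mm) and raise a geometry
error otherwise.

## Numerical conventions

These choices are fixed and asserted by the unit tests:

* **Voxel indexing is 1-based**, following the R ecosystem. The center of
  voxel $(i,j,k)$ is at `origin + (index - 1) * spacing` (mm). File geometry
  comes from the NIfTI header (pixdim and the qform/sform translation).
* **Union bounding box**: confusion counts are taken inside the smallest
  axis-aligned box enclosing the positive voxels of both masks. This leaves
  TP, FP, FN unchanged and only reduces TN, so TNR and RI stay informative
  instead of saturating near 1 on the CT background. `fullRegion()` exposes
  whole-volume counts for comparison.
* **Surfaces** are the centers of mask voxels with at least one
  face-adjacent (6-connectivity) neighbor outside the mask or outside the
  grid, converted to mm with the voxel spacing.
* **Distance statistics** are computed on the pooled vector
  $v = (d(A,B), d(B,A))$ of nearest-neighbor distances between surfaces,
  with $A$ the ground truth. `HD_std` is the *population* SD of $v$;
  `HD_95` uses `quantile(type = 7)` (linear interpolation); `MDA` is the
  one-directional `mean(d(A,B))`. Nearest-neighbor search is a blocked
  vectorized exhaustive computation, bit-for-bit equal to a naive
  double loop (same IEEE accumulation order); no spatial index is used.
* **Undefined ratios** (0/0) and distances of empty masks are `NaN`, never
  silently dropped at computation time; cohort summaries skip `NaN` and
  report the contributing count `n`.

## The KDE QA model

Per approved contour, the HU values of the masked voxels are density-
estimated with a Gaussian kernel and Scott's-rule bandwidth
$h = \hat\sigma\, n^{-1/5}$ (overridable), evaluated on a shared grid
(default $-1024$ to $1600$ HU, step 2). A zero-variance sample falls back to
a bandwidth of one grid step with a warning. The per-organ **baseline** is
the pointwise mean of the reference KDEs with bounds mean $\pm$ 2 sample SD
($n-1$ denominator); the lower bound is clipped at 0 since densities cannot
be negative.

The **agreement value** of a test KDE is the fraction of grid points whose
density lies inside the closed envelope $[\mathrm{lower}, \mathrm{upper}]$.
Two support modes exist:

* `support = "full"` (default): the denominator is the whole grid,
  including zero-density tails that agree trivially.
* `support = "restricted"`: the denominator is restricted to grid points
  where the baseline mean density exceeds $10^{-6}$, which removes the
  trivially agreeing tails and is stricter on wide grids.

In a matched-population simulation (100 patients with i.i.d. normal HU
samples of $n = 5000$, grid spanning the mean $\pm 4$ SD, an 80/20
reference/held-out split, 20 seeds) the mean held-out agreement and the
pooled pointwise coverage of the $\pm 2$ SD envelope are both $\approx$ 0.95
(`matchedCohortAgreement()`; `scripts/acceptance.R` reproduces this).

A QA run (`qaContourSet()`, or `qaFromFiles()` / the `qa` CLI subcommand)
flags organs whose agreement falls below a threshold (default 1.0, i.e. a
100 % requirement, adjustable) as `review`; organs without a baseline are
reported as `no_baseline` rather than raising an error.

## Cohort analysis

The 13 metrics are stored in a long table (`patient_id`, `organ`, `method`,
`metric`, `value`). `summarizeByOrgan()` / `summarizeByPatient()` give
NaN-skipping means and sample SDs; `differenceMatrix()` gives signed
mean differences (method2 − method1) per organ × metric;
`pairedTest()` runs two-sided paired t-tests on per-patient differences
(complete pairs only) and names a winner at level $\alpha$ using the metric
family's direction (higher overlap / lower distance is better). Degenerate
cases follow fixed conventions: fewer than 2 pairs gives `NaN` p-value and
`no_difference`; zero-variance nonzero differences give $p = 0$ and an
infinite t-statistic; all-zero differences give `no_difference`.

## Synthetic phantom generator

`generatePhantom()` rasterizes a `PhantomSpec` — ellipsoidal "organs" with
organ-typical Gaussian HU distributions on a Gaussian background — on a
default $64 \times 64 \times 48$ grid with $1 \times 1 \times 1.5$ mm
spacing. All randomness flows from one integer seed; `simulateCohort()`
derives per-patient seeds as `seed + patient index` and models anatomical
variation with one uniform radius-scale factor per patient. Perturbation
models (`perturbMask()`): ball dilation/erosion, rigid translation in mm,
boundary noise (per-voxel flips at the surface), and a seeded random-
direction mislabel shift. Magnitude 0 is the identity for every kind, and a
perturbation that empties a mask is an error.

The generator exists to provide closed-form oracles and dose-response
checks, not anatomical realism: translated equal spheres recover the
analytic lens-volume DSC, surface Hausdorff distances track the imposed
displacement, and agreement values decrease monotonically in contamination
fraction and translation magnitude.

## Problem sizes and performance

Designed-for sizes: volumes up to $\sim 256^3$ voxels, surfaces up to a few
$10^4$ points, KDE grids of a few thousand points, cohorts of hundreds of
patients. The exhaustive blocked nearest-neighbor search is quadratic in
surface size; at the sizes above it completes in seconds.

## Limitations

* The agreement value's dose-response to contamination is monotone for
  contaminant modes shifted by about 5 baseline SDs. For far larger shifts
  (e.g. 10 SD) extreme contamination ($\phi \ge 0.8$) drives the test
  density to near zero around the baseline mode, where it trivially
  re-enters the zero-clipped lower bound in low-density regions, and
  agreement can tick back up. This is a genuine property of envelope
  agreement, not an implementation artifact.
* The full-grid agreement denominator counts trivially agreeing
  zero-density tails; use `support = "restricted"` when comparing across
  grids of different extents.
* No resampling or registration: masks must share the image grid exactly.
* HU baselines assume roughly stationary acquisition protocols; a scanner
  or reconstruction change shifts HU distributions and requires rebuilding
  baselines.
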