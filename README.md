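# contourQA

Quantitative evaluation and knowledge-based quality assurance (QA) of
automatic organ segmentations on CT.

Auto-segmentation tools (atlas-based, deep-learning) propose organ-at-risk
contours that clinicians must check before radiotherapy planning. This
package provides the two halves of that workflow:

1. **Evaluation against ground truth** — when a clinician-approved contour
   exists, score the automatic contour with six volumetric overlap metrics
   and seven Hausdorff-family surface-distance metrics.
2. **Knowledge-based QA without ground truth** — when no reference contour
   exists (the routine clinical case), score a new contour by comparing the
   kernel density estimate (KDE) of the Hounsfield-unit (HU) values inside
   it against a per-organ baseline built from previously approved contours.
   Contours whose HU density falls outside the baseline's ±2 SD envelope are
   flagged for review.

A deterministic synthetic CT phantom generator makes the whole pipeline
testable end to end without any clinical data.

## The metrics

Overlap metrics are computed from confusion counts (TP, FP, FN, TN) inside
the **union bounding box** — the smallest rectangular volume enclosing the
positive voxels of both masks. Restricting to this box leaves TP/FP/FN
unchanged but keeps TN from saturating on the vast empty background of a CT
volume (on a 128³ volume, TNR and RI of a clearly misplaced small organ both
exceed 0.999 when computed over the full volume; inside the box they drop
below 0.95 and become informative).

| Metric | Definition |
|---|---|
| DSC | 2·TP / (2·TP + FP + FN) |
| JAC | TP / (TP + FP + FN) = DSC / (2 − DSC) |
| TPR | TP / (TP + FN) |
| TNR | TN / (TN + FP) |
| PPV | TP / (TP + FP) |
| RI  | (TP + TN) / (TP + TN + FP + FN) |

Distance metrics are statistics of the pooled nearest-neighbor distances
between the two mask surfaces (boundary-voxel centers under 6-connectivity,
in mm, honoring anisotropic voxel spacing): HD_max (the classical Hausdorff
distance), HD_95, HD_mean, HD_median, HD_min, HD_std, and MDA (mean distance
to agreement, ground-truth surface to test surface only). Any 0/0 ratio and
any distance involving an empty mask is NaN, and NaN values are skipped (and
counted) in all cohort aggregation.

## The QA model

For each organ, per-patient KDEs (Gaussian kernel, Scott's-rule bandwidth)
of the HU values inside approved contours are evaluated on a shared grid.
The baseline is the pointwise mean ± 2 sample SD of those curves, with the
lower bound clipped at 0. A new contour's **agreement value** is the
fraction of grid points where its KDE lies inside the envelope; organs below
a configurable threshold (default 1.0, i.e. 100 %) are flagged `review`. In
a matched-population simulation (80 reference / 20 held-out patients), the
mean held-out agreement is ≈ 0.95 — the two-sigma rule's expected coverage.

## Worked example

```r
library(contourQA)

## a synthetic CT with ground-truth organ masks
spec <- defaultPhantomSpec()
ph   <- generatePhantom(spec, seed = 7)

## evaluate a misplaced contour against ground truth: all 13 metrics
test <- perturbMask(ph$masks$brain, "translate", 2, direction = c(1, 0, 0))
round(compareMasks(ph$masks$brain, test), 4)
#>      DSC       JAC       TPR       TNR        RI       PPV    HD_std
#>   0.8759    0.7792    0.8759    0.9122    0.8972    0.8759    0.7116
#>   HD_min HD_median   HD_mean       MDA     HD_95    HD_max
#>   0.0000    1.0000    0.9132    0.9132    2.0000    2.0000

## knowledge-based QA without ground truth: per-organ KDE baseline
grid   <- kdeGrid(-300, 150, 1)
curves <- lapply(1:20, function(i) {
  p <- generatePhantom(spec, seed = 100 + i)
  fitKDE(extractHU(p$image, p$masks$kidney_L), grid)
})
bl  <- buildBaseline(curves, organ = "kidney_L")
bad <- perturbMask(ph$masks$kidney_L, "translate", 6)
qaContourSet(ph$image, list(ph$masks$kidney_L, bad), list(kidney_L = bl),
             threshold = 0.8, patientId = "p007", method = "atlas")
#>   patient_id    organ method  agreement threshold verdict
#> 1       p007 kidney_L  atlas 0.87804878       0.8    pass
#> 2       p007 kidney_L  atlas 0.02882483       0.8  review
```

Cohort-level analysis: `summarizeByOrgan()`, `summarizeByPatient()`,
`differenceMatrix()` (signed method2 − method1 means per organ × metric),
`pairedTest()` and `winLossTally()` (paired two-sided t-tests per cell with
the metric family's better-direction convention).

## Command line

A thin CLI wraps the exported functions (NIfTI masks named
`<patient>_<organ>_<role>.nii[.gz]`):

```sh
# sim.yaml:  perturbations: { atlas: { kind: translate, magnitude: 2 } }
Rscript inst/cli/contourqa.R simulate --out-dir cohort --n 20 --seed 1 \
        --config sim.yaml
Rscript inst/cli/contourqa.R compare --gt-dir cohort/ground_truth \
        --test-dir cohort/atlas --method atlas --out metrics.csv
Rscript inst/cli/contourqa.R build-baseline --cohort-dir cohort \
        --out baselines.json
Rscript inst/cli/contourqa.R qa --image cohort/images/p001_ct.nii.gz \
        --masks-dir cohort/atlas --baseline baselines.json --out qa.csv
```

Options may also be given in a YAML file via `--config`; command-line flags
take precedence.

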