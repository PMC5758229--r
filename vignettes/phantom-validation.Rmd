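---
title: "Delineating metabolic tumor volume on digital PET/CT phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating metabolic tumor volume on digital PET/CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmtv)
```

## The problem

Metabolic tumor volume (MTV) — the physical volume of the
FDG-avid part of a lesion on a PET scan — is a prognostic
marker in lung cancer, but its value depends heavily on how the lesion is
delineated. Threshold-based automated methods behave very differently on
small, low-uptake, ground-glass (nonsolid) nodules than on large solid
tumors, because PET resolution (4–5 mm full width at half maximum) smears
small objects (the partial-volume effect, PVE) and because low-uptake
lesions sit barely above lung background.

`petmtv` implements four widely used automated delineation methods, the
recovery-coefficient (RC) calibration that corrects thresholds for PVE, a
CT-based anatomical reference volume (CTV) pipeline, and an evaluation
framework that scores each method by its percentage volume error against
CTV. Because clinical images cannot be shipped, the package also provides
a synthetic digital PET/CT phantom generator with analytic ground truth,
so every claim the package makes about method behaviour is demonstrated on
data whose true volume is known exactly.

## The four delineation methods

All four methods operate inside a user bounding box (VOI) on an SUV
volume, threshold at some absolute SUV `T`, and keep the 26-connected
component of supra-threshold voxels containing the SUVmax voxel.
Comparisons are inclusive (voxels exactly at `T` are kept).

* **T42%** — `T = 0.42 · SUVmax`. The classical percentage threshold,
  calibrated historically on high-contrast sphere phantoms; reliable for
  large, high-uptake solid lesions.
* **T42%×RC** — `T = 0.42 · RC(d) · SUVmax`, where `RC(d) ≤ 1` is the
  recovery coefficient looked up by the lesion's CT long diameter `d`.
  Lesions above 30 mm are treated as recovery-complete (`RC = 1`), so the
  method coincides with T42% there. Lowering the threshold compensates
  the PVE signal loss of small lesions — at the cost of swallowing
  background when contrast is low.
* **AT-AIA** — adaptive iterative thresholding. Starting from the T42%
  threshold, each iteration forms the connected region at the current
  threshold and re-thresholds at 42% of a blended reference level that
  weights SUVmax against the region's SUVmean with weight 0.5:
  `T ← 0.42 · (0.5 · SUVmax + 0.5 · SUVmean(R))`.
  On a homogeneous lesion the reference level equals SUVmax and the
  method reduces exactly to T42%; on heterogeneous or blurred lesions the
  region mean pulls the reference level — and with it the absolute
  threshold — down, adapting to the lesion's own uptake distribution.
  We deliberately apply the 42% fraction to the *blend* rather than
  iterating the blend itself as the threshold: the blend is bounded below
  by the current threshold for any region (every region voxel is at or
  above it), so using it directly as the next threshold produces a
  strictly increasing sequence that collapses onto the SUVmax plateau for
  every input — a degenerate method that could not reproduce the
  documented accuracy of adaptive iterative delineation on large solid
  lesions. Iteration stops at an exact region fixed point, when the
  threshold moves less than `tol` (default 1% of SUVmax), on a detected
  threshold cycle, or at `max_iter` (default 100); non-convergence is
  reported rather than hidden.
* **AT40%** — background-adaptive thresholding,
  `T = BG + 0.40 · (SUVmax − BG)`, with mean background SUV `BG`
  measured in a spherical ROI mirrored across the mid-sagittal plane into
  the contralateral lung. This is the only method that uses background
  information, which is what makes it robust exactly where the others
  fail: lesions whose uptake barely exceeds lung background.

## Recovery-coefficient calibration

RCs are measured on a simulated hot-sphere phantom (six spheres, 10–37 mm,
in a uniform background at an 8:1 activity ratio) with the
threshold-isocontour technique: `C_hot` is the mean SUV inside the
isocontour at a fraction of the sphere's maximum, `C_bg` the pooled mean
of three 15 mm background ROIs far from any sphere, and
`RC = (C_hot/C_bg) / (a_hot/a_bg)`. The table is interpolated linearly
in diameter, clamped at its ends, capped at 1, and overridden by the
`RC = 1` rule above 30 mm.

The isocontour fraction defaults to **0.7**. This is a deliberate choice:
at contrast `c` the blurred profile at the true sphere boundary sits at
`(1 + (c−1)/2)/c` of the peak — 0.5625 at 8:1 — so a 50% isocontour lies
*outside* the sphere and averages in the blurred skirt, biasing RC low by
a bound that does not vanish for spheres much larger than the PSF
(closed-form value 0.883 for the 37 mm sphere at 4.5 mm FWHM). A 70%
isocontour keeps the ROI inside the sphere and restores the physically
required asymptote `RC → 1` as `d/FWHM → ∞` (0.94 at 37 mm). The
fraction is configurable for users matching a historical scanner table.

## CT reference and stratification

The CT reference volume is the largest 26-connected component at or above
−700 HU inside the VOI (between lung parenchyma at ~−850 HU and
ground-glass attenuation at ~−600 HU). Nodule consistency is typed by the
fraction `f` of mask voxels at or above −300 HU: `f ≥ 0.9` solid,
`f ≤ 0.05` nonsolid, otherwise part-solid; the cuts separate the three
classes cleanly for dense-core fractions between ~5% and ~90%. The long
diameter is the maximal pairwise distance between voxel centres
(exhaustive over boundary voxels, which contain every extreme point, so
it equals the full scan). Lesions are stratified at 20 mm (the T1a/T1b
cut, inclusive to "small") and at SUVmax 2.0 (inclusive to "low"; early
lung adenocarcinoma runs lower than the usual 2.5 malignancy cut).

Evaluation uses the percentage volume error
`%VE = (MTV − CTV)/CTV × 100`; errors within ±50% (inclusive) count as
accurate — a band wider than the ±30% sometimes used, appropriate for
small, heterogeneous, low-uptake lesions. MTV–CTV agreement is banded by
Pearson correlation (0.21–0.40 poor, 0.41–0.60 moderate, 0.61–0.80 good,
0.81–1.00 excellent; at or below 0.20 "none") and inter-observer
reliability by ICC(2,1) — two-way random effects, absolute agreement,
single rater, the form that matches what reproducibility of a measured
volume means — with cuts at 0.40 (poor below) and 0.75 (good above).

## The phantom generator

Lesions are spheres of uniform pre-blur activity on a uniform lung
background; part-solid nodules carry a concentric dense core holding 30%
of the lesion volume (CT-visible only — activity is uniform across the
lesion). The PET image is rendered on an oversampled grid (per-axis
factor bringing the voxel near 0.8 mm, at most 4; native when the grid is
already fine or blur is off), convolved with an isotropic Gaussian PSF
via FFT using the analytic transfer function (which conserves total
activity exactly), block-averaged to the PET grid, and degraded with
seeded additive Gaussian SUV noise. The CT volume is rendered at
1.25 mm; the ground-truth mask is the analytic sphere support sampled at
CT voxel centres and the true volume is exact voxel arithmetic on it.

Default study conditions emulate a stage I lung adenocarcinoma cohort:
133 lesions (16 nonsolid, 30 part-solid, 87 solid), PET grid
40×24×24 at 3.27 mm (elongated so the mirrored background ROI falls in
clean "contralateral" lung), PSF 4.5 mm FWHM, noise SD 0.05 SUV,
diameters uniform 8–35 mm for every type, pre-blur activities uniform
per type (nonsolid 1.2–2.4, part-solid 1.5–4.5, solid 2.5–8.0 SUV) on a
0.4–0.6 SUV background. The activity ranges are where the free choice
lives: no per-type uptake distributions are established beyond the
low/high split, so they were set once to place nonsolid lesions mostly at
or below SUVmax 2 and solid lesions above it, reproducing the strong
type–uptake association (generated cohorts show Spearman ≈ 0.71 between
type rank and measured SUVmax) that motivates type-first method
selection.

What the generator does **not** emulate: irregular lesion shapes (spheres
keep the ground truth analytic), intralesional uptake heterogeneity,
scanner physics (sinograms, OSEM reconstruction, attenuation,
position-dependent resolution), respiratory motion, and anatomical
background structure (vessels, airways, chest wall). Consequences:
passing tests demonstrate the *relative* behaviour of the methods under
partial volume and low contrast — overestimation of small low-contrast
lesions by fixed thresholds, the advantage of background-adaptive
thresholding there, near-perfect CT typing — but absolute accuracies are
optimistic relative to clinical images, where AT40% would not reach 100%
within-±50% and CT consistency typing would not be error-free.

## Numerical choices

* Thresholds compare with `≥`, so a uniform lesion at exactly the
  threshold is kept whole.
* Masks are restricted to the 26-connected component containing the
  SUVmax voxel, preventing disjoint background islands inside the box
  from inflating MTV; connected components are grown by mask-restricted
  separable dilation.
* VOIs are given in mm and snapped *outward* to whole voxels (half-open
  voxel convention, voxel centres at `(i−0.5)·spacing`).
* MTV and CTV are voxel counts times the exact voxel volume — never
  fitted or estimated.
* The RC lookup clamps below the smallest tabulated diameter (no
  extrapolation) and caps at 1; `RC = 1` above 30 mm takes precedence
  over interpolation.
* Degenerate inputs error early and loudly: empty VOIs, background ROIs
  touching the lesion box or a hot sphere, background mean at or above
  SUVmax, constant ICC matrices, CT boxes with nothing above threshold.

## Method recommendation

The per-stratum recommendation follows type first — nonsolid and
part-solid lesions to AT40%, solid lesions to AT-AIA — with small or
low-uptake solid lesions tie-broken to AT40%, the background-aware
choice; where strata conflict (e.g. a large nonsolid lesion) type wins,
since type is both the strongest determinant of method behaviour and the
easiest to read off the CT.

## Problem sizes

The shipped tests and the acceptance script use the full 133-lesion
default cohort for the stratified comparison, a 40-lesion noiseless
cohort for the two-observer (±2 mm background-ROI jitter) reliability
experiment, 100 seeded 16³ blurred phantoms for the convergence suite,
twenty 32³ random volumes for the oracle-equivalence checks, and 48³
1 mm grids for the volume-recovery experiment. A full study runs in
about a minute and a half on one core.

## Limitations

Beyond the generator simplifications above: the RC table is derived from
the simulated phantom, not from a physical scanner, so it cannot be
compared against any particular scanner's published table; the AIA
iteration is our reading of "adaptive iterative weighting of SUVmax and
SUVmean" — vendor implementations are proprietary and may differ in
region definition or stopping rule; and survival analysis, registration,
and DICOM ingestion are out of scope.
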