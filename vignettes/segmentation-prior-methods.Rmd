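---
title: "Building tissue-wise multi-angle segmentation priors for PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building tissue-wise multi-angle segmentation priors for PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemip)
```

## The problem and the approach

Whole-body FDG-PET/CT tumor segmentation in 3D is hard where it matters
most: small lesions and lesions with low tracer uptake are swamped by class
imbalance and low contrast. A maximum-intensity projection (MIP), by
contrast, accentuates focal uptake — every hot voxel wins its ray — so a 2D
segmenter working on MIPs sees lesions far more clearly than a 3D network
sees them in the volume.

`tissuemip` implements a pipeline that exploits this. CT is decomposed into
bone, lean-tissue, adipose and air compartments by Hounsfield-unit (HU)
thresholding, and the SUV volume is masked per compartment to give
tissue-wise channels. All channels are projected into 2D MIPs at 18 viewing
angles (10° steps over [−90°, 90°)). A 2D segmenter marks lesions in each
projection; the per-angle 2D masks are then *backprojected* — extruded along
their ray direction and inverse-rotated into the volume frame — summed over
angles, multiplied voxel-wise by SUV, normalized to [0, 1] and floored at
the 5th percentile of the positive values. The result is a *segmentation
prior*: a 3D map, aligned with the PET/CT grid, of where independent viewing
angles agree that tumor is present, weighted by uptake. The prior is
supplied as a third input channel (alongside CT and SUV) to a 3D segmenter,
pulling its attention to lesions it would otherwise miss.

## Tissue decomposition

A raw-HU CT voxel $i$ is classified by four fixed windows:

* bone: $i \ge 200$
* lean tissue: $-29 \le i \le 150$
* adipose tissue: $-190 \le i \le -30$
* air: $i < -190$

The windows are disjoint but deliberately not exhaustive: HU in the open
gap $(150, 200)$ — and the sliver $(-30, -29)$ — belong to no compartment.
We preserve these gaps exactly as stated rather than closing them, because
the unclassified voxels remain fully visible in the original CT/SUV
channels, and closing the gap would silently change the stated windows.
Boundary inclusivity is literal: $-190$ is adipose, air is strictly below.

Classification always runs on **raw HU**, before the modelling window of
$[-100, 250]$ HU is applied — the thresholds $-190$ and $200$ lie outside
that window, so clipping first would destroy them. Intensity conditioning
for models is a fixed affine map of the clip window to $[0,1]$ (CT
$[-100,250]$, SUV $[0,15]$), not per-volume min–max, so intensities remain
comparable across subjects. Masked SUV channels are normalized with the
same fixed SUV window; masked CT channels use an affine map over the
channel's occupied HU range, since each tissue channel has its own
physically distinct range. Both choices are configurable.

## Projection geometry

The volume is rotated about the craniocaudal (z) axis and reduced by
maximum along the anterior–posterior (y) axis, so angle 0 is the standard
coronal whole-body MIP. Numerical choices that matter:

* **Padding.** The rotated frame is padded to the in-plane diagonal, so no
  anatomy leaves the field of view at oblique angles. Output images are
  (z extent × padded extent); the geometry (angle, source shape, pad) rides
  along as an attribute for inversion.
* **Interpolation.** Intensity MIPs use bilinear interpolation during
  rotation. Angles that are multiples of 90° are special-cased to exact
  nearest-neighbour resampling (the rotation is an axis permutation there),
  which removes needless interpolation blur and gives exact test anchors.
* **Rounding.** All geometric rounding is round-half-up, not IEEE
  round-half-even; with half-integer center offsets, round-half-even would
  collapse adjacent voxels onto one column and leave stripes.
* **Binary masks.** Mask-mode projection does *not* resample the volume:
  each foreground voxel is rotated forward and marks the column it rounds
  to. Backprojection evaluates the *same* forward map per output voxel.
  This makes backprojection the exact adjoint of projection: the
  backprojection of a projected mask provably contains every voxel that
  produced it, at every angle — the property the fused overlap count
  depends on. An inverse-resampling implementation of mask projection
  cannot guarantee this (a rotated unit cell need not contain a lattice
  point).
* Rotation operates in index space; the in-plane spacing of the target
  grids is isotropic (2.04 × 2.04 mm), so no spacing correction is applied.

With the oracle 2D segmenter (which returns the projected ground truth),
every truth voxel therefore attains the full overlap count of 18, truth
lesion centroids sit far above the prior's background, and the prior
localization score is exactly 1 — these are invariants the test suite
asserts, not tuned outcomes.

## The prior

Fusion sums the 18 binary backprojections (voxel overlap count 0–18) and
multiplies by SUV, so agreement across angles and high uptake reinforce
each other. Normalization divides by the global maximum; the noise floor
then zeroes voxels at or below the 5th percentile of the *strictly
positive* values. We compute the percentile over positive voxels only:
most voxels lie outside every extrusion and are exact zeros, so an
all-voxel percentile would typically remove nothing. The textual order —
normalize, then remove the floor — is implemented as stated and covered by
a regression test; an all-voxel mode is available by flag. A fully constant
positive support is a degenerate input (the percentile equals every value);
real fused volumes are never constant because of SUV variation.

## Deterministic reference segmenters

The 2D and 3D neural backends used at cohort scale (UNet++ in 2D; 3D UNet,
dynUNet, nnUNet in 3D) are out of scope here: they are GPU- and
external-data-bound, and nothing about the geometric contribution depends
on them. They can be plugged in behind the `segmenter2d` contract and the
`model3d_spec` backend slot; the recorded 2D training configuration
(Dice+Focal loss, Adam, learning rate 1e-4, weight decay 1e-5, dropout
0.20, batch size 1) and 3D patching (160³ patches, 0.25 overlap) are kept
as configuration defaults. When several 2D backends are supplied,
`ensemble_segmenter()` combines them by pixel-wise union — maximizing
detected lesions and leaving false-positive filtering to the members.

In their place, two deterministic instruments make the pipeline fully
testable:

* `threshold_segmenter(t)` thresholds the SUVorgMIP channel — a reasonable
  lower bound on a trained 2D network.
* `oracle_segmenter(stack)` returns the projected ground truth — the exact
  upper bound.
* `reference_segmenter3d()` thresholds SUV at 2.5 in baseline mode; in
  prior modes, voxels with positive prior support are accepted already at
  SUV 1.5. The two thresholds are phantom-calibrated test instruments
  (background 1.0 ± 0.3 after noise truncation; the hard-case lesion sits
  at 2.0), not clinical claims, and are configurable.

This pairing reproduces the *direction of effect* of the prior: a lesion
with uptake between the two thresholds is invisible to the baseline but
recovered in prior mode, so lesion-wise recall strictly improves on every
hard-case phantom, and a paired two-sided Wilcoxon signed-rank test over a
12-phantom suite is significant at 0.05.

## The phantom generator

The generator emulates the statistical structure the pipeline assumes, at
the target voxel spacing 2.04 × 2.04 × 3.00 mm: a body-shaped elliptic
cylinder of lean tissue (40 HU) with an adipose shell (−100 HU) and a bone
rod (400 HU) in surrounding air (−800 HU); SUV background 1.0 inside the
body and near zero outside; optional physiologic hot spots (SUV 8) that are
*not* tumor; and non-overlapping ellipsoidal lesions with isotropic-mm
radii converted to anisotropic voxel radii through the spacing. Noise is
additive Gaussian, truncated at ±3σ (15 HU on CT, 0.1 SUV), so each
compartment stays inside its HU window and the SUV separation between
lesions and background is guaranteed by construction. The default grid is
48 × 48 × 64 voxels — large enough for several lesions and a realistic
padded projection frame, small enough that the full 20-phantom property
suites run in seconds.

The hard-case preset pins lesion 1 to radius 4.7 mm (≈ 0.43 ml: below 1 ml
but above the 0.3 ml analysis filter) and lesion 2 to SUV 2.0 (above
background, below the baseline threshold) — the small and low-uptake
scenarios the prior exists for.

What the phantoms do **not** emulate: PET reconstruction noise (Poisson
sinogram statistics, partial-volume blur), organ-specific uptake patterns,
respiratory motion, and irregular lesion shapes. Passing phantom suites
therefore demonstrates the geometric and statistical correctness of the
pipeline, not clinical performance on patient data.

## Evaluation suite

* Voxel level: Dice (empty/empty defined as 1, one-sided empty as 0, so
  cohort loops never crash), HD95 and average symmetric surface distance in
  physical mm. Surfaces are mask voxels with a face-adjacent (6-neighbour)
  background voxel; HD95 pools both directed distance sets before the 95th
  percentile; ASD is the mean over the pooled sets — the standard symmetric
  definitions. Both are undefined (NA with a warning) when a mask is empty.
* Lesion level: 27-connected components; components ≤ 0.3 ml are discarded
  on **both** the truth and prediction side; a truth lesion counts as
  detected on ≥ 1 voxel of overlap with the (filtered) prediction — the
  most permissive defensible rule, overridable via `min_overlap_voxels`.
* Stratification: per-lesion Dice inside the lesion's padded bounding box,
  grouped by metabolic tumor volume with per-disease presets (lymphoma
  1/2/4/14 ml, lung 2/3.5/7.3/23 ml, melanoma 1/1.5/3/8 ml; a volume at the
  top boundary goes to V5, matching the convention that V5 is "≥ b₄").
  SUVmean groups use caller-supplied boundaries — no published defaults
  exist, so none are invented.
* Method comparison: false-negative confusion matrices over truth lesions
  (detected-by-A × detected-by-B), and a paired two-sided Wilcoxon
  signed-rank test. Zero differences are dropped; for n ≤ 30 the p-value
  comes from the exact sign-flip distribution computed by dynamic
  programming over (doubled) midranks, so tied differences — common for
  recall fractions — are handled exactly rather than by a normal
  approximation.

## Worked example

```{r example}
ph <- generate_phantom(hard_case_config(seed = 7))
stack <- build_projection_stack(ph$suv, truth = ph$truth)
prior <- build_segmentation_prior(stack, oracle_segmenter(stack), ph$suv)
prior_localization_score(prior, ph$truth)

base <- reference_segmenter3d(model3d_spec("baseline"), ph$ct, ph$suv)
with_prior <- reference_segmenter3d(model3d_spec("prior_2"), ph$ct, ph$suv,
                                    prior = prior)
evaluate_segmentation(base, ph$truth, suv = ph$suv)
evaluate_segmentation(with_prior, ph$truth, suv = ph$suv)
```

## Known limitations

* The reference segmenters are deliberately simple; absolute Dice values on
  phantoms say nothing about trained-network performance on patient data.
* Mask-mode projection marks one column per voxel; a sub-voxel-thin
  structure can appear one column narrower than bilinear intensity MIPs
  suggest. The containment guarantee is unaffected.
* Backprojection extrudes across the full anterior–posterior extent, so a
  prior built from few angles contains long streaks; with 18 angles the
  SUV weighting and noise floor suppress them, but single-angle priors are
  streak-dominated by design.
* `resample_to_common_grid` uses separable trilinear (or nearest) sampling
  with edge clamping; it does not low-pass filter before heavy
  downsampling.
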