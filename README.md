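# tissuemip

Tissue-wise multi-angle projection priors for whole-body FDG-PET/CT tumor
segmentation.

## What it does and for whom

3D tumor segmentation in whole-body PET/CT struggles exactly where clinical
stakes are highest: small lesions and lesions with low FDG uptake. In a 2D
maximum-intensity projection (MIP), however, focal uptake is accentuated —
every hot voxel wins its ray — so lesions that are nearly invisible in the
volume stand out in projections. `tissuemip` is for researchers building or
evaluating segmentation-prior pipelines that exploit this:

1. **Tissue decomposition.** The CT volume (raw HU) is split into bone
   (HU ≥ 200), lean tissue (−29 ≤ HU ≤ 150), adipose tissue
   (−190 ≤ HU ≤ −30) and air (HU < −190) masks, and the SUV volume is
   masked per compartment into tissue-wise channels.
2. **Multi-angle MIPs.** All SUV channels are projected at 18 angles (10°
   steps over [−90°, 90°)), along with the projected ground-truth lesion
   masks for training/oracle use.
3. **2D segmentation.** A pluggable 2D segmenter marks lesions per angle;
   deterministic reference backends (SUV threshold, ground-truth oracle)
   ship with the package, and trained networks plug in behind the same
   contract.
4. **Segmentation prior.** Per-angle masks are backprojected (extruded
   along the ray and inverse-rotated), summed over angles — giving a voxel
   overlap count 0..18 — multiplied voxel-wise by SUV, normalized to
   [0, 1], and floored at the 5th percentile of the positive values:

   `prior(v) = floor_5%( overlap(v) · SUV(v) / max )`

5. **3D segmentation.** The prior joins CT and SUV as a third input
   channel (`baseline` = CT+SUV, `prior_1`/`prior_2` = +prior from a
   1-channel / 5-channel 2D stage); a deterministic reference 3D segmenter
   demonstrates the prior's benefit without any training.
6. **Evaluation.** Dice, HD95 and average surface distance (mm);
   lesion-wise precision/recall over 27-connected components > 0.3 ml;
   MTV-stratified lesion Dice; false-negative confusion matrices between
   methods; paired two-sided Wilcoxon signed-rank tests.

A synthetic phantom generator (body-shaped CT compartments, low-uptake SUV
background, physiologic hot spots, configurable ellipsoidal lesions at
2.04 × 2.04 × 3.00 mm spacing) makes every stage testable without patient
data, including a hard-case preset with a sub-1 ml lesion and a lesion
barely above background.

## Worked example

```r
library(tissuemip)

ph    <- generate_phantom(hard_case_config(seed = 7))
stack <- build_projection_stack(ph$suv, truth = ph$truth)
prior <- build_segmentation_prior(stack, oracle_segmenter(stack), ph$suv)

prior_localization_score(prior, ph$truth)
#> [1] 1

base <- reference_segmenter3d(model3d_spec("baseline"), ph$ct, ph$suv)
wp   <- reference_segmenter3d(model3d_spec("prior_2"), ph$ct, ph$suv, prior = prior)

evaluate_segmentation(base, ph$truth, suv = ph$suv)
#> <eval_report> Dice 0.405 | HD95 40.45 mm | ASD 13.96 mm
#>   lesions: 4 truth, 3 predicted; TP 2 FN 2 FP 1; recall 0.50 precision 0.67

evaluate_segmentation(wp, ph$truth, suv = ph$suv)
#> <eval_report> Dice 0.753 | HD95 39.60 mm | ASD 7.62 mm
#>   lesions: 4 truth, 5 predicted; TP 4 FN 0 FP 1; recall 1.00 precision 0.80
```

Reading the numbers: the localization score 1 says the prior highlights
every truth lesion above its background. The baseline SUV-threshold
segmenter misses the low-uptake and one low-ish lesion (recall 0.50); with
the prior as an extra channel both are recovered (recall 1.00) and voxel
Dice rises from 0.41 to 0.75. The single FP in both reports is the
phantom's physiologic hot spot, which by design is not tumor.

A thin CLI over the same functions lives at `inst/cli/tissuemip.R`
(subcommands `phantom`, `decompose`, `prior`, `segment3d`, `evaluate`, all
reading/writing NIfTI).

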