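---
title: "Synthetic CT for metastatic bone: models, phantoms and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT for metastatic bone: models, phantoms and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(boneSCT)
```

## The problem

MRI-guided high-intensity focused ultrasound (MR-HIFU) palliation of bone
metastases needs the cortical and cancellous bone distribution in treatment
position, but bone is best depicted by CT, which is acquired days to months
earlier and in a different pose. Synthetic CT (sCT) — a CT-like volume in
Hounsfield units regressed from the treatment MR images — sidesteps the
inter-scan registration problem because it is intrinsically aligned with
the MR frame. boneSCT packages the whole assessment loop for this idea:
simulate paired dual-echo MR / CT bone volumes with osteolytic,
osteoblastic or mixed lesions; normalize, register and patch them; train a
3D patch-based UNet-like regression network under leave-one-out
cross-validation; and score sCT against CT with the standard metric suite
(MAD, MD, Dice after 150-HU extraction, surface RMSD).

No clinical images ship with the package: the phantom generator is a
first-class, tested module that emulates the study conditions, and a small
per-case table of published cohort metrics ships as a text fixture so that
the summarization/reporting path is verifiable independently of training.

## The phantom generator

### Geometry

One case is a stylized long bone / hemipelvis: an oval cortical tube
(aspect 0.75, one-sided lateral flare toward the cranial end, like a
trochanter) with cancellous interior and a central marrow cavity,
embedded in an elliptic muscle body with a subcutaneous fat ring inside a
water background. The default grid is 64×64×64 voxels at 1×1×2 mm. The
oval cross-section and one-sided flare are deliberate: a circular tube is
rotationally symmetric about its axis, which would make rigid registration
of its surface ill-posed; real bones are asymmetric, and the phantom must
be too for the ICP stage to be testable.

Lesions are spheres placed in the bone interior: osteolytic (tissue HU
offset −400 from cancellous), osteoblastic (+400), or mixed (lytic core,
blastic rim). An optional cortical breach removes the contiguous window of
cortical shell adjacent to the lesion, as lytic destruction does. The
ground-truth bone mask is cancellous + cortical + intra-bone lesion
labels; the lesion mask is the lesion labels.

### CT rendering

Per voxel, HU is the tissue-table mean plus Gaussian noise with the
tissue's SD, then blurred with a 0.8-mm Gaussian point-spread kernel so
boundary voxels carry partial-volume values. The default table (cortical
1200±50, cancellous 300±50, marrow −50±20, muscle 40±15, fat −100±20,
water 0±10 HU) straddles the 150-HU bone-extraction threshold, which is
what makes that threshold meaningful on the phantom. With noise, blur and
texture disabled the rendering is an exact per-label lookup — the clean
limit that several exactness tests use.

**Trabecular texture.** Real trabecular bone interleaves with fatty
marrow; pelvic and femoral interiors span roughly −50…400 HU rather than
sitting at a single value. The generator therefore draws a smooth seeded
Gaussian field (3-mm correlation length), maps it through its CDF to a
per-voxel *marrow fraction* up to 0.7 inside the cancellous compartment,
and blends both the CT properties and the MR tissue parameters with the
same field. Without this heterogeneity the 150-HU extraction saturates the
bone mask and Dice overlap degenerates: a classifier that marks *every*
voxel as bone becomes near-optimal, and comparisons against it measure
luck, not learning. The shared field keeps the heterogeneity coherent
across modalities, so it is learnable — exactly as fatty marrow is visible
in T1-weighted MR.

### MR rendering

Each voxel evaluates the radiofrequency-spoiled gradient-echo steady-state
magnitude
$$S(TE) = PD\,\sin\alpha\,\frac{1-E_1}{1-\cos\alpha\,E_1}\,
e^{-TE/T_2^*}\,\bigl|(1-f\!f) + f\!f\,e^{i\,2\pi\,\Delta f\,TE}\bigr|,
\qquad E_1 = e^{-TR/T_1},$$
at the protocol defaults TE = 2.1/4.2 ms, TR = 7 ms, flip 10°, 1.5 T. The
fat–water shift is fixed at Δf = 220 Hz (≈3.5 ppm at 1.5 T), which places
the first echo near opposed phase (fat–water angle ≈166°) and the second
near in phase — so voxels with fat fraction 0.5 are strictly darker on
echo 1 than echo 2, a property the test suite asserts. Gaussian noise is
added on the magnitude (2 % of the maximum signal by default) and clamped
at zero; at this SNR the Gaussian/Rician distinction is immaterial and
Gaussian keeps the noiseless limit exact.

Both MR echoes receive the same 0.8-mm PSF as the CT by default. This is a
modeling decision worth stating plainly: with a perfectly sharp MR and a
blurred CT, the value of a boundary voxel in CT depends on sub-voxel
geometry that the binary-sharp MR does not carry, so the regression target
at interfaces would be irreducibly ambiguous — an artifact of the
simulation, not of the method. Matching the effective resolutions (as
resampling a clinical CT onto the MR grid does in practice) keeps the
MR→CT map well-posed.

The tissue MR parameters (PD, T1, T2*, fat fraction) are stand-ins chosen
for realistic 1.5-T T1-weighted contrast — bright fat and marrow, mid
muscle, near-void cortex — and are config-exposed, not claimed as measured
values.

### Randomness

Each case derives three independent seed streams (geometry/texture, CT
noise, MR noise) from one case seed, so toggling noise never changes
anatomy. Cohorts are bitwise reproducible from one cohort seed; the
default 9-case cohort uses the exact composition 3 osteolytic /
4 osteoblastic / 2 mixed in seeded random order.

## Preprocessing

MR magnitudes are clipped at the per-volume 95th percentile (type-7,
linear interpolation between order statistics) and mapped affinely with
0 → −1 and the clip value → +1; magnitude data have a physical zero, so
the lower anchor is 0, not the minimum. The clip emulates suppressing
hyperintense transducer-bath fluid. CT maps \[−1024, 3071\] HU affinely to
\[−1, 1\] after clipping, and this normalization is exactly invertible —
`denormalizeCT()` is what turns network output back into HU.

Patches are 24³ voxels, sampled at random origins with at least 80 %
of windows intersecting the bone mask (evaluation happens in bone; the
sampling ratio is a config knob the source protocol does not specify).
Augmentation acts on whole volumes *before* patch extraction — rotating
24³ cubes would lose their corners — with coronal/sagittal flips (p = ½
each, exact involutions) and a rotation uniform in ±45° about the
feet–head axis (linear interpolation for images, nearest neighbour for
masks, applied identically to every channel). Augmentation precedes
normalization so out-of-field fill stays at each modality's physical zero.

## Rigid registration

Bone surfaces are the centers of mask voxels with at least one 6-neighbour
outside the mask, in physical mm (anisotropy-aware). ICP alternates
nearest-neighbour correspondence (moving→fixed, ties to the lowest index)
with the closed-form Kabsch/Umeyama fit (cross-covariance SVD with a
reflection guard), starting from a centroid-aligning translation; the
logged RMS sequence is non-increasing by construction and iteration stops
when it changes by under 10⁻³ mm (defaults: 100 iterations, clouds
regularly subsampled above 4000 points). On noiseless point clouds
misaligned by ≤30°/≤20 mm the recovery is exact to <0.1° and <0.1 mm; on
voxelized mask surfaces accuracy is limited by the ~1-mm grid. Resampling
under the recovered transform uses cubic B-spline interpolation with the
exact prefilter (masks: nearest neighbour; out-of-field: −1024 HU for CT,
0 otherwise). The deformable stage that a clinical pipeline would add
afterwards is exposed only as a plug-in hook (`deformableHook` in
`pipelineConfig()`): on phantoms the ground-truth misalignment is rigid,
so rigid recovery is the testable core.

## The translation network

A 3-level 3D UNet-like encoder–decoder: two 3³ conv + ReLU blocks per
level, 2³ max-pool down, 2³ transposed-conv up, skip concatenation, and a
linear 1³ head on the normalized CT scale. Two input channels carry the
two echoes. No normalization layers are used: at desk scale (base 8
filters, single-patch optimizer steps) batch statistics are high-variance
and hurt reproducibility, and the plain conv+ReLU network with He
initialization converges cleanly on this task. The loss is the mean
absolute error (L1) on normalized intensities, optimized by Adam; the
reference learning rate is 10⁻⁴, while the desk-scale configuration uses
2×10⁻³ with single-patch steps (2 epochs × 12 patches per volume) — at a
fixed patch budget, more small steps move a small network further than
fewer averaged ones. Since no deep-learning framework is available in
this R stack, the convolutions (im2col + BLAS GEMM), their backward
passes, pooling and Adam are implemented in the package itself and
verified against finite differences.

Full-volume inference tiles the volume with stride patchSize/2, averages
overlapping predictions with uniform weights (which provably preserves
constants — asserted to 10⁻⁶ HU), denormalizes to HU and clips to
\[−1024, 3071\].

Leave-one-out cross-validation over n cases: fold i tests case i,
validates on case (i mod n)+1, trains on the rest; every case is tested
exactly once and can never leak into its fold's training set
(structurally asserted). The validation case selects the best checkpoint
(epochs are fixed; no early stopping, for reproducibility). All fold
randomness derives from one seed.

## Evaluation

Within the bone mask: MAD = mean |sCT−CT| and MD = mean (sCT−CT) on raw
HU (MD < 0 means the sCT underestimates); Dice and the surface RMSD are
computed between the 150-HU (inclusive) extractions of sCT and CT. The
lesion region uses the undilated lesion mask for MAD/MD/DSC, and dilates
it by a 3-cm Euclidean margin (anisotropy-aware) for the surface distance
only. The RMSD is directed — sCT surface to CT surface — matching the
phrase "sCT-to-CT surface distance"; a symmetric variant sits behind a
flag. Surfaces are 6-connectivity boundary voxel centers; distances come
from an exact anisotropic Euclidean distance transform
(Felzenszwalb–Huttenlocher, per-axis with physical spacing) and equal the
brute-force all-pairs computation to 10⁻⁹ on every random instance the
suite draws. Two empty extractions give Dice 1 with a warning (perfect
agreement on absence — a fully lytic lesion must not crash the pipeline);
an empty extraction on one side yields a flagged `NA` RMSD, never a
silent 0.

Cohort summaries are means and *sample* (n−1) standard deviations per
metric and region. The n−1 divisor is pinned by the shipped reference
table: the bone-MAD column summarizes to 116 ± 26 HU with the sample
divisor, while the population divisor would print 25. Two documented
internal inconsistencies of the reference values are left as they are:
the bone MD column averages +14 while the published summary prints −14
(a sign slip; this package fixes the sCT−CT convention), and the lesion
RMSD column averages 2.91 against a printed 2.73; no assertion is placed
on either quantity.

## Problem sizes and numerical choices

The shipped configurations are desk-scale by design: nine 64³ phantoms,
base-8-filter network, 2 epochs × 12 single-patch steps per volume per
fold — roughly a minute per fold on one core — which is enough for the
learning-sanity property (held-out bone DSC above the fold's untrained
initialization in ≥8/9 folds) without pretending to clinical accuracy.
The overfit demonstration uses a single noiseless phantom and 10 epochs,
reaching a training L1 below 0.05 (≈100 HU); with noise enabled the noise
floor (~0.015 normalized) would sit under a similar but shifted curve. No
claim is made that phantom MAD/DSC values match the clinical cohort —
the phantoms lack real anatomy, registration error, and interscan change,
which is precisely why the clinical per-case table ships as the fixture
for the aggregation layer.

Other numerical decisions: percentile type 7; CT range treated as
exhaustive (clipped before mapping); inclusive ≥150 threshold; maxpool
ties resolve to the first voxel in column-major order; ICP nearest
neighbours are one-directional without trimming (adequate for clean
phantom surfaces, a documented limitation for real data); B-spline
prefilter poles truncated at 10⁻¹² relative accuracy.

## Limitations

The phantom is stylized, not patient anatomy: no bias field, no motion,
no true trabecular microstructure, no transducer bath (only the
95th-percentile clip it motivates), rigid-only misalignment. Passing
tests therefore demonstrate that the pipeline's machinery — physics-
consistent simulation, exact normalization algebra, verifiable metrics,
convergent ICP, a learning network, leak-free cross-validation and
faithful cohort aggregation — behaves as specified; they do not certify
clinical image quality. The network is CPU-sized; scaling `baseFilters`
and the patch budget up is a configuration change, not a code change.

## A worked run

```{r}
cohort <- makeCohort(9, phantomSpec(), seed = 42)
cv <- loocv(cohort,
            networkConfig(baseFilters = 8),
            trainConfig(learningRate = 2e-3, epochs = 2, batchSize = 1,
                        patchesPerVolume = 12, seed = 5),
            baseline = TRUE)
report(cv$reports, cv$summary)
```

The same run, end to end with artifacts on disk, is
`runPipeline(pipelineConfig(seed = 42, outDir = "out"))`, and the
reference-table path is `report(referenceCohortMetrics())`.
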