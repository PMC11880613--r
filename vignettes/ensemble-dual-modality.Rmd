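---
title: "Ensemble dual-modality 3D brain-tumor segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble dual-modality 3D brain-tumor segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gliomas present in multi-parametric MRI as nested sub-regions with
modality-dependent contrast: peritumoral edema is bright on T2 and
FLAIR, the enhancing rim is bright on post-contrast T1 (T1ce), and the
necrotic core is dark on T1ce.  No single sequence shows all three
sub-regions at once, which is why automated segmentation pipelines
ingest several co-registered sequences per patient.  `xaimri`
implements one complete pipeline of this kind: BraTS-layout ingestion,
region-of-interest (ROI) cropping, 3D U-Net segmentation from stacked
modality channels, feature-level ensembling of two dual-modality
models, the six standard voxel-wise evaluation metrics, and volumetric
Grad-CAM explanations — plus a seeded multimodal phantom generator so
that the entire pipeline is testable on one CPU without any data
download.

## Preprocessing: ROI cropping to a standard cube

Input volumes are 240 × 240 axially with 155 slices.  The pipeline
standardizes them to (128, 128, 128):

1. **Bounding box.** On the T1 volume, axial slice 77 (0-based; the
   middle of 0..154) is thresholded at intensity > 0 and the tight
   bounding box `x1, x2, y1, y2` of the foreground is taken.  T1 is
   used because it shows the brain/background edge clearly; the middle
   slice gives a central view wide enough to enclose the brain on all
   other slices.  The box is computed **once per subject** and applied
   unchanged to all four modalities and the mask.
2. **Depth slab.** Slices `[13, 141)` are retained — the half-open
   0-based interval is the convention that yields exactly 128 slices,
   trimming the near-empty extremes of the stack.
3. **In-plane resize** to 128 × 128: bilinear for intensities,
   nearest-neighbor for labels (so resizing can never invent a label
   value).  The box is not padded to a square first; aspect ratio may
   change under the resize.  Coordinates are (row = x, col = y).
4. **Intensity normalization.** Per-volume min–max over suprathreshold
   voxels to [0, 1], clipped; constant volumes map to zero.  (Min–max
   is this package's choice; normalization schemes vary across
   pipelines in this area.)
5. **Label remapping.** Raw labels {0, 1, 2, 4} (the label-3 gap is a
   BraTS convention) are remapped bijectively to contiguous {0, 1, 2,
   3} as a softmax head requires; the inverse map is recorded so
   predictions can be exported back to the raw dialect.

Everything here is deterministic — there is no RNG anywhere in the
preprocessing module — and all indices are 0-based with half-open
intervals.

## The segmentation network

`build_unet()` constructs a 3D U-Net: `depth_levels` encoder stages of
two 3×3×3 convolutions + ReLU, 2× max-pooling between stages, filters
doubling from `base_filters`; a symmetric decoder using 2×2×2
transposed convolutions with skip concatenation; dropout at the
bottleneck and after each decoder stage; a 1×1×1 convolution to
`n_classes` with a per-voxel softmax.  Defaults are 4 stages, 16 base
filters, dropout 0.2.  Published U-Net variants differ in stage count,
filter widths and upsampling flavor, so these are declared defaults —
all configurable — rather than claims about any particular network;
the package's property tests (softmax normalization, shape
equivariance, parameter-count tally, seeded reproducibility) do not
depend on exact capacity.

No deep-learning framework is used: the convolution, transposed
convolution and max-pooling kernels and their hand-derived backward
passes are implemented in C++ (single-threaded, bit-deterministic),
glued by a small define-by-run tape in R.  Every backward pass is
verified against central finite differences in the test suite, which
is the strongest correctness evidence available for gradient code.

## Training protocol

`train_config()` defaults encode the full-scale training protocol:
batch size 4,
at most 40 epochs, Adam at learning rate 1e-4, early stopping when the
validation loss has not improved for 5 consecutive epochs, and
checkpointing of the weights with the smallest validation loss (which
the returned model carries).  Interpretations where the protocol is
silent:

* "did not improve" = strict decrease (`min_delta = 0`, configurable);
  ties on the minimum are resolved to the first epoch.
* Optimizer: Adam, the near-universal companion of lr 1e-4.
* Loss: categorical cross-entropy over the four classes by default.
  Because tumor sub-regions can be vanishingly rare at phantom scale,
  the trainer also offers inverse-frequency weighted cross-entropy
  (`"wce"`), macro soft-Dice (`"dice"`) and a Dice+CE compound
  (`"dicece"`); an optional global gradient-norm clip stabilizes large
  weighted gradients.
* No data augmentation; subject-level splitting only (the 70/15/15
  split uses floor/floor/remainder sizes, so 369 subjects give
  258/55/56).

## The ensemble dual-modality model

`build_ensemble()` takes the two pre-trained dual-modality models
(canonically T2+T1ce and T1ce+FLAIR), removes each output layer, and
concatenates the *penultimate activations* — the only feature maps
adjacent to the removed layers.  The concatenation feeds a fusion
convolution (3×3×3, stride 1, 16 output channels, ReLU, shape-
preserving padding — required for voxel-wise softmax at input
resolution), then a fresh 1×1×1 softmax head.  The union input tensor
stores each modality once (T2, T1ce, FLAIR; T1ce is shared) and a
routing table feeds each base its expected channel order.

Base weights are frozen by default (`freeze_base = TRUE`): the models
are combined as *pre-trained* artifacts and only the fusion and head
parameters train.  Because the frozen base features of each subject
never change, they are precomputed once per training run.  Full
fine-tuning is available via `freeze_base = FALSE`, which places both
base bodies on one tape (verified by finite differences).

## Metrics and their aggregations

Six voxel-wise metrics are reported: accuracy, mean IoU, Dice,
precision, sensitivity, specificity.  The aggregation conventions are
the subtle part: benchmark tables in this area routinely print Dice
near 0.98 next to mean IoU near 0.60, which is only mutually
consistent if Dice is computed *globally* over all classes including
the dominant background while mean IoU is a *macro* average of
per-class IoU.  The package therefore defaults to:

* `dice_coef`: global Dice over flattened one-hot encodings (soft
  probabilities supported); per-class Dice available via
  `mode = "per_class"`.
* `mean_iou`: macro mean of per-class IoU over all classes; a class
  with an empty union contributes 1 (perfect agreement on the empty
  set), flagged and skippable.
* `precision`/`sensitivity`/`specificity`: micro one-vs-rest sums,
  with an explicit `NA` marker on zero denominators, never a silent 0.
* `accuracy`: the voxel match fraction.  For more than two classes the
  textbook formula (TP+TN)/(TP+TN+FP+FN) applied to summed one-vs-rest
  counts is *not* the match fraction (the pooled TN term inflates it);
  the match fraction is what standard training frameworks report and
  the only reading consistent with "fraction of correctly classified
  voxels", so it is the default, while the raw count arithmetic
  remains available as `accuracy_from_counts()`.

All metrics are verified against an independent brute-force
implementation to 1e-12 on a thousand random volume pairs.

## Grad-CAM for 3D segmentation

Grad-CAM needs a scalar score; segmentation emits one score per voxel
per class.  The default reduction is the mean logit of the target
class over the voxels *predicted* as that class — a standard
seg-Grad-CAM choice — falling back (flagged) to the whole-volume mean
when the predicted region is empty.  Channel weights are spatial means
of the score gradient at the target layer (default: the last
convolution before the output head; for ensembles, the fusion
convolution, making the fused representation the explanandum); the
ReLU-rectified weighted activation sum is upsampled trilinearly to the
input grid and min–max normalized to [0, 1] with an all-zero guard.
Heat maps are invariant to positive rescaling of the score by
construction.  `overlay()` blends a jet-colormapped map over the
grayscale background at opacity `alpha` and can render side-by-side
panels of input slices next to the overlay.

## The phantom generator

`generate_subject()` emulates the BraTS data contract: per subject,
four modality volumes and a labeled mask on a 240 × 240 × 155 grid
(configurable down to small test geometries), an ellipsoidal brain,
and nested tumors in the raw label dialect.  Each tumor is a triplet
of concentric anisotropic ellipsoids — edema shell (label 2), necrotic
core (1), enhancing center (4) — so the enhancing ⊆ core ⊆ whole-tumor
nesting holds *by construction*.  Shell fractions are random per tumor
(core U(0.50, 0.80)·r, enhancing U(0.25, core−0.15)·r, axis ratios
U(0.7, 1.3)): with fixed fractions the sub-region boundaries would be
a deterministic function of the outer shape and a single-modality
network could resolve all classes geometrically, defeating the design
goal that fusion be genuinely informative.  A tumor must fit entirely
inside the brain mask; a placement that cannot be achieved in 100
tries is an error.

Voxel intensities are tissue-class means from a contrast table plus
Gaussian noise (σ = 10 by default against class separations of 20–80),
clipped at zero, in arbitrary units (real intensity scales are
scanner-dependent and not part of the data contract).  The default
table encodes the clinical contrast structure *and* a deliberate
ambiguity pattern:

| tissue      | T1  | T1ce | T2  | FLAIR |
|-------------|-----|------|-----|-------|
| background  | 0   | 0    | 0   | 0     |
| brain       | 100 | 100  | 80  | 70    |
| core        | 90  | 60   | 120 | 110   |
| edema       | 95  | 100  | 160 | 150   |
| enhancing   | 95  | 180  | 120 | 110   |

T1 has little tumor contrast; T1ce confounds edema with brain; T2 and
FLAIR confound core with enhancing.  Consequently no single modality
separates all classes, T2+T1ce and T1ce+FLAIR each separate
everything, and T2+FLAIR still cannot split core from enhancing — so
the clinically expected ordering emerges by construction (T2+FLAIR the
weakest pair, T1ce the strongest single modality).

What the phantoms deliberately do **not** model: MRI physics (bias
fields, partial-volume effects, k-space artifacts), non-ellipsoidal
tumor shapes, multifocal interaction, or non-glioma pathologies.
Passing tests on phantoms therefore demonstrate the correctness and
internal consistency of the pipeline and the qualitative value of
modality fusion — not clinical performance.

## Scaled-down study design

Full-scale training (seven 128³ models on 369 subjects) is a GPU-scale
undertaking; the package's tests and the acceptance script instead run
a scaled-down twin chosen once as this package's study conditions:
48 × 48 × 40 phantoms preprocessed to 32³ (reference slice 20, depth
slab [4, 36)); tumor radius fraction 0.40–0.55 of the brain radius so
that sub-region voxel *fractions* match full-scale data rather than
shrinking quadratically with the grid; nine subjects split 5/2/2;
U-Nets with 2 stages and 6 base filters (dropout 0.1); weighted
cross-entropy, Adam at lr 1e-2, batch 1, at most 40 epochs with
patience 15; ensemble fusion trained up to 25 epochs.  At this scale a
training run takes about a minute on one CPU, and the fusion-benefit
comparison (ensemble mean IoU vs the best single modality, averaged
over three seeds) completes in minutes while preserving the full-scale
study's structure: the same preprocessing, the same architecture
family, the same protocol shape, the same metrics.

## Numerical and degenerate-input choices

* Resampling uses center-aligned coordinates
  (`src = (i + 0.5)·n/size − 0.5`); identity resizes are exact, and
  2× nearest upsampling replicates labels in 2×2 blocks.
* Softmax and cross-entropy are computed with max-subtraction; the
  per-voxel probability sums are tested to 1e-5.
* Min–max normalization of constant volumes returns zeros; Grad-CAM
  maps that are identically zero stay zero rather than dividing by a
  zero range.
* Argmax tie-breaks are fixed to the first class, keeping every
  prediction path bit-deterministic.
* All seeds fan out from a global seed through a stable string hash
  (`stage name → 31-bit seed`), so each pipeline stage is
  independently reproducible and no seed exceeds 2³¹.

## Known limitations

* The hand-rolled CNN engine is single-threaded C++; it is fast enough
  for the desk-scale geometries it targets, not for 128³ training,
  which would need hours per model on CPU.
* Full-scale BraTS2020 benchmark numbers are out of reach at desk
  scale by design (they need the external download and GPU-scale
  training of seven models); the package reproduces the *structure* —
  nine scenarios, six metrics, ensemble on top — and the qualitative
  ordering on phantoms.
* Aggregation conventions behind published benchmark tables are rarely
  stated; the defaults here are chosen for mutual consistency of the
  printed magnitudes, and every metric exposes its alternative
  aggregation.
* Grad-CAM's visual appearance depends on the chosen layer and score;
  the package asserts the tumor-localization property, not visual
  identity with any published figure.
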