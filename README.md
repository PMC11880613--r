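# xaimri

Ensemble dual-modality 3D brain-tumor segmentation from multi-parametric
MRI, with explainable heat maps — implemented end-to-end in R.

## What this package does, and for whom

Gliomas appear differently in each MRI sequence: edema is bright on T2
and FLAIR, the enhancing rim lights up on post-contrast T1 (T1ce), the
necrotic core is dark on T1ce.  `xaimri` is for researchers who want a
fully inspectable, CPU-runnable implementation of a modern multimodal
segmentation pipeline in the BraTS mold:

* **Phantoms** — a seeded generator of multimodal 3D subjects
  (240 × 240 × 155 by default) with nested tumor sub-regions
  (enhancing ⊆ core ⊆ whole tumor) and realistic modality contrasts, so
  everything below is testable without downloading patient data.
* **I/O** — BraTS-layout NIfTI discovery and reading, label remapping
  {0,1,2,4} → {0,1,2,3} with a recorded inverse, subject-level 70/15/15
  splits (369 subjects ↦ 258/55/56).
* **Preprocessing** — ROI cropping: bounding box from T1 slice 77,
  depth slab [13, 141), in-plane resize to 128 × 128 (bilinear /
  nearest), min–max normalization; output (128, 128, 128) per modality.
* **Model** — a configurable 3D U-Net (encoder–decoder, skip
  connections, dropout, softmax head) over stacked modality channels.
  The convolution kernels and their backward passes are written in
  C++/Rcpp; gradients are verified by finite differences in the tests.
* **Training** — mini-batch Adam (batch 4, ≤ 40 epochs, lr 1e-4),
  early stopping on validation loss with patience 5, best-weights
  checkpointing.
* **Ensemble** — the package's centerpiece: strip the output layers of
  the two best dual-modality models (T2+T1ce and T1ce+FLAIR),
  concatenate their penultimate feature maps, fuse with a 3×3×3
  stride-1 16-channel ReLU convolution, finish with a softmax head.
  Base weights are frozen by default; full fine-tuning is a flag.
* **Metrics** — accuracy, mean IoU (macro over classes), Dice
  (global), precision, sensitivity, specificity (micro one-vs-rest),
  with explicit aggregation metadata and an `NA` marker for undefined
  ratios.  For voxel sets $A$ (prediction) and $B$ (truth):

  $$\mathrm{Dice} = \frac{2|A \cap B|}{|A| + |B|}, \qquad
    \mathrm{IoU} = \frac{|A \cap B|}{|A \cup B|}$$

* **Grad-CAM** — volumetric relevance maps for segmentation models
  (channel weights = spatial means of the score gradient at a chosen
  layer; ReLU-rectified weighted activations, trilinearly upsampled,
  normalized to [0, 1]) and slice overlays rendered to PNG.

The methods vignette (`vignettes/ensemble-dual-modality.Rmd`) explains
every design decision, the phantom's contrast table, and what the
desk-scale experiments do and do not demonstrate.

## Worked example

Generate a small cohort of phantoms, preprocess, train two dual-modality
models, fuse them, and evaluate:

```r
library(xaimri)

spec <- phantom_spec(grid_shape = c(48, 48, 40), noise_sigma = 10,
                     tumor_radius_frac_range = c(0.40, 0.55), seed = 103)
subjects <- lapply(sprintf("p%02d", 1:9), function(id) generate_subject(spec, id))
pcfg  <- preprocess_config(reference_slice = 20, depth_range = c(4, 36),
                           target_inplane = 32)
preps <- lapply(subjects, preprocess_subject, config = pcfg)

fit <- function(mods, seed = 1) {
  ds <- make_dataset(preps, mods)
  m  <- build_unet(unet_config(in_channels = length(mods), depth_levels = 2,
                               base_filters = 6, dropout_rate = 0.1), seed = seed)
  m$modalities <- mods
  tc <- train_config(batch_size = 1, max_epochs = 40, learning_rate = 1e-2,
                     patience = 15, loss = "wce", clip_norm = Inf, seed = seed)
  train(m, ds[1:5], ds[6:7], tc)
}
dual_a <- fit(c("T2", "T1ce"))
dual_b <- fit(c("T1ce", "FLAIR"))

ens <- build_ensemble(dual_a$model, dual_b$model, ensemble_config(), seed = 1)
dse <- make_dataset(preps, ens$modalities)   # union order: T2, T1ce, FLAIR
tre <- train(ens, dse[1:5], dse[6:7],
             train_config(batch_size = 1, max_epochs = 25, learning_rate = 1e-2,
                          patience = 10, loss = "wce", clip_norm = Inf, seed = 1))
print(evaluate(tre$model, dse[8:9]))
```

On the two held-out phantoms this prints (seed-reproducible):

```
Segmentation metrics (65536 voxels):
  accuracy     0.992126
  mean_iou     0.722024
  dice_coef    0.992126
  precision    0.992126
  sensitivity  0.992126
  specificity  0.997375
  per-class IoU: 0.9941 0.5290 0.6571 0.7079
```

Accuracy and global Dice sit near 1 because background dominates the
volume; the macro mean IoU is the discriminative number — here the
fused model recovers all three tumor sub-regions (per-class IoU well
above zero for core, edema and enhancing tumor), which no single
modality manages on these phantoms.  A Grad-CAM explanation of the
fused model:

```r
x  <- stack_modalities(preps[[8]], ens$modalities)
hm <- compute_gradcam(tre$model, x, gradcam_config(target_class = 3))
overlay(hm, preps[[8]]$volumes$T1ce, slice_index = 16, alpha = 0.5,
        file = "gradcam.png", panels = preps[[8]]$volumes["T2"])
```

writes a panel of the T2 slice beside the T1ce slice with the heat map
over it; on this subject the mean relevance is 0.073 inside the true
tumor versus 0.001 outside — the map concentrates on the lesion.

There is also a one-call orchestrator,
`run_pipeline(run_config(seed = 1, out_dir = "run"))`, and a thin CLI
(`inst/cli/xaimri.R`) with `synth`, `preprocess`, `evaluate` and
`pipeline` subcommands.

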