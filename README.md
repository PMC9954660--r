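# rdaunet

Slice-wise segmentation of the bladder and bladder lesions on abdominal CT,
built around a residual-dense attention U-Net. The package implements the
complete pipeline for researchers working with windowed CT slices and
binary expert masks:

* **Preprocessing** — Hounsfield-unit windowing (`apply_hu_window()`,
  default soft-tissue window −160..240 HU), bilinear/nearest resizing of
  image/mask pairs (`resize_pair()`, 512→224 by default), overlay QC
  (`overlay_check()`), seeded 8:2 train/validation splits
  (`split_dataset()`), 16-bit PNG + manifest storage, and a minimal DICOM
  reader.
* **Augmentation** — five joint affine transforms with fixed ranges
  (scale {1.0, 1.2}, rotation ±15°, shift ±10 px, shear ±5°, horizontal
  flip at 50%), applied identically to image and mask;
  `expand_dataset()` triples a corpus (712 → 2136).
* **Model** — a five-level encoder–decoder: two residual stages, three
  dense stages (growth rate 14), four max-pools, and additive attention
  gates on every skip connection. The frozen default configuration
  instantiates with exactly **13,053,861 trainable parameters**
  (`count_parameters()`), the architecture's reference fingerprint. The
  convolutional engine (im2col/GEMM convolutions, batchnorm, transposed
  convolutions, reverse-mode gradients, ADAM) is implemented in the
  package with RcppArmadillo.
* **Training** — seeded minibatch ADAM (lr 10⁻³, batch 8), per-epoch
  loss/pixel-accuracy curves for both sets, best-validation
  checkpointing, `tidy()`/`glance()`/`autoplot()` accessors.
* **Metrics** — pixel accuracy, Dice, IoU, average Hausdorff distance
  (exact Euclidean distance transform) and rank-based ROC-AUC, each
  validated against brute-force oracles:

  ACC = (TP+TN)/(TP+TN+FP+FN),  DSC = 2·TP/(FP+2·TP+FN),
  IoU = TP/(FP+TP+FN),  AVGDIST = (mean_G d(g,S) + mean_S d(s,G))/2.

* **Phantoms** — a seeded generator of CT-like slices with exact ground
  truth over a taxonomy of organ shapes (round, elongated, irregular,
  near-bone, near-top) and lesion patterns (none, single/multiple large,
  small, irregular), so the whole pipeline is testable without clinical
  data.

## Worked example

Train a reduced-width network (same topology, `base_width = 8`) on 200
synthetic phantoms at 64×64 and evaluate on the held-out fifth:

```r
library(rdaunet)

ds  <- generate_dataset(200, phantom_spec(side = 64), seed = 11)
sp  <- split_dataset(ds$organ, ratio = 0.8, seed = 3)
set.seed(101)
net <- build_rda_unet(rda_net_config(base_width = 8))
fit <- train_model(net, sp, train_config(epochs = 20, seed = 5), verbose = TRUE)
#> ...
#> epoch  19  loss 0.1148  acc 0.9962  val_loss 0.1164  val_acc 0.9910
#> epoch  20  loss 0.1060  acc 0.9967  val_loss 0.1050  val_acc 0.9943

pred <- lapply(sp$val, function(p) predict_mask(fit, p$image))
gt   <- lapply(sp$val, function(p) p$mask)
summarise_metrics(evaluate_masks(pred, gt))
#> # A tibble: 1 × 4
#>     acc   dsc   iou avgdist
#>   <dbl> <dbl> <dbl>   <dbl>
#> 1 0.994 0.961 0.926  0.0469
```

The held-out Dice of 0.96 means the predicted organ masks overlap the
ground truth almost completely; the average Hausdorff distance of 0.05 px
says the remaining disagreement is confined to sub-pixel boundary
wobble. `autoplot(fit)` draws the loss/accuracy curves and
`attention_maps(fit, image)` exposes the per-level attention coefficients.

A command-line front end over the same functions is shipped at
`inst/cli/rdaunet.R` (subcommands `phantom`, `preprocess`, `augment`,
`train`, `predict`, `evaluate`, `model-summary`).

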