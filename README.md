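# rdaunet

Automatic segmentation of the liver and hepatic lesions in abdominal CT,
built around a **residual-dense-attention U-Net**: a U-shaped
encoder-decoder whose encoder stages combine residual blocks
(`H(x) = F(x) + x`) with densely connected blocks (each layer consumes the
concatenation of all previous outputs, adding a fixed growth rate of
channels), and whose decoder gates every skip connection with an additive
attention gate producing per-pixel coefficients `α ∈ (0, 1)` that suppress
irrelevant image regions.

The package is aimed at researchers who want to study this architecture
family end to end — data conditioning, layer graph, training dynamics,
evaluation — on a single CPU, with every component open to inspection:

* **Phantoms** — a deterministic generator of CT-like slices (HU-valued,
  512×512 by default) with one connected "liver" region and 0–5 "lesion"
  discs nested strictly inside it, plus exact ground-truth masks, so the
  whole pipeline is testable with no external data.
* **Preprocessing** — Hounsfield-unit windowing (clamp to `[hu_min, hu_max]`,
  rescale to [0, 1]), bilinear/nearest resizing to the network grid, seeded
  8:2 dataset splitting, contour overlays, DICOM-series-to-NIfTI conversion.
* **Architecture** — a configurable factory (`arch_config()`, `rda_unet()`)
  with a per-node shape/parameter manifest and a parameter counter tied to
  an analytic oracle in the tests. All layers and gradients are implemented
  in the package (im2col convolutions in C++), verified against finite
  differences.
* **Metrics** — pixel accuracy `(TP+TN)/total`, Dice `2TP/(2TP+FP+FN)`,
  IoU `TP/(TP+FP+FN)` (so `IoU = DSC/(2−DSC)`), average Hausdorff distance
  between boundary point sets, and ROC AUC via the rank statistic — each
  pinned to a brute-force oracle in the tests.
* **Pipeline** — seeded Adam training with best-validation checkpointing,
  bit-exact checkpoint round-trips, leakage-checked evaluation, ggplot2
  learning curves and four-panel overlay reports, broom-style `tidy()` /
  `glance()` accessors, and a thin command-line front end
  (`inst/cli/rda.R`).

## Worked example

Train a small liver model on phantoms and evaluate the held-out split:

```r
library(rdaunet)

dir <- file.path(tempdir(), "phantoms")
generate_dataset(phantom_config(image_size = 128), n = 80, seed = 100,
                 out_dir = dir)
manifest <- read_manifest(dir)

arch  <- arch_config(input_size = 64, depth = 3, base_filters = 8)
cfg   <- train_config_demo(seed = 11, target = "liver")  # 15 epochs, Adam 1e-3
model <- train(arch, cfg, manifest, verbose = TRUE)
#> epoch   1  train loss 0.5103 acc 0.7535 | val loss 0.5943 acc 0.7648
#> ...
#> epoch  15  train loss 0.2089 acc 0.9727 | val loss 0.2118 acc 0.9626

evaluate_run(model, manifest)$aggregate
#> # A tibble: 1 × 8
#>     acc   dsc   iou avgdist   auc n_cases n_missing_avgdist n_missing_auc
#>   <dbl> <dbl> <dbl>   <dbl> <dbl>   <int>             <int>         <int>
#> 1 0.963 0.914 0.852    1.39 0.987      16                 0             0
```

Reading the output: on the 16 held-out phantoms the model reaches a mean
Dice overlap of 0.91 with the true liver masks (IoU 0.85 — note
`iou = dsc/(2-dsc)` holds row by row), pixel accuracy 0.96 (flattered by
the large background, as accuracy always is), and a mean boundary error
(average Hausdorff distance) of 1.4 pixels on the 64-px network grid.
`tidy(model)` returns the per-epoch history, `autoplot(model)` the learning
curves, and `predict(model, slice)` a binary mask on the input grid.

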