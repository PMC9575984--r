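# hemseg

Quantitative segmentation and volumetry of intracerebral hemorrhage (ICH)
on head CT, for imaging scientists who need a fully testable,
CPU-reproducible reference implementation of the modern ICH pipeline:

* a **synthetic head-CT phantom generator** (air / brain / skull / lesion,
  ellipsoid, lobulated and multifocal shapes) with exact analytic lesion
  volumes, so every downstream component is verifiable without clinical
  data;
* CT **preprocessing**: in-plane resampling to a 512×512 matrix, automatic
  head-window slice selection, Hounsfield windowing to [−60, 140] HU and
  normalization to [0, 1];
* a from-scratch **2-D attention-gated focus U-Net**: a U-Net whose encoder
  fuses a lossless space-to-depth ("focus") branch with the pooled path at
  each downsampling, and whose skip connections are gated by learned
  sigmoid attention maps. Forward pass, backpropagation and RMSprop are
  implemented in the package (R + compiled kernels) — no deep-learning
  framework required;
* **training** with the standard protocol (RMSprop, batch 2, 7:1:2 case
  split, learning-rate ×0.1 trigger after two stalled validation epochs);
* **segmentation metrics**: Dice = 2TP/(FP+2TP+FN), IoU = TP/(FP+TP+FN),
  sensitivity, PPV, and the 95% Hausdorff surface distance in mm
  (robust percentile mode and literal 0.95 × HD mode);
* **volumetry**: voxel counting V = Σᵢ X·Y·T·Wᵢ (mL) and an automated
  clinical Coniglobus estimate V = A·B·C/2 measured caliper-style from the
  mask, with method agreement via ICC(2,1) and OLS regression.

Report-level functions return tibbles and chain with the pipe; fitted
agreement objects support `tidy()` / `glance()`, and reports have
`autoplot()` methods.

## Worked example

Generate a small phantom cohort, train a scaled-down network, and measure
volumes:

```r
library(hemseg)

man <- generate_cohort(20, "cohort/", seed = 11, shape = "ellipsoid",
                       matrix = 64, n_slices = 14,
                       spacing_mm = c(2.5, 2.5, 4),
                       semi_axes_range = c(14, 22))

model <- build_network(net_config(depth = 3, base_channels = 16), seed = 11)
fit   <- train(model, man, train_config(lr0 = 3e-4, epochs = 15,
                                        batch_size = 2, seed = 11))
glance(fit)
#> # A tibble: 1 × 7
#>   epochs best_val_loss final_val_loss final_val_dice final_lr n_train n_val
#>    <int>         <dbl>          <dbl>          <dbl>    <dbl>   <int> <int>
#> 1     15       0.00870         0.0131          0.995  0.00003      14     2
```

`best_val_loss` is the best soft-Dice + cross-entropy validation loss seen
during the run; `final_val_dice` is the per-case Dice on validation
phantoms — at this scale the network segments the hyperdense lesion almost
perfectly within a dozen epochs. Measure a held-out case:

```r
cs  <- read_case(man$image_path[1]) |> window_normalize()
gt  <- read_mask(man$mask_path[1])
pm  <- predict_case(fit$model, cs)
evaluate_case(pm, gt)
#> # A tibble: 1 × 7
#>   case_id        dice   iou sensitivity   ppv hd95_mm degenerate
#>   <chr>         <dbl> <dbl>       <dbl> <dbl>   <dbl> <lgl>
#> 1 case_001_mask 0.989 0.978       0.997 0.981       0 FALSE

mask_volume_ml(gt)       # 16.9 mL  — reference voxel-count volume
coniglobus_volume(gt)    # 21.0 mL  — clinical A·B·C/2 estimate
```

The Coniglobus read is 24% high here: at 2.5 mm pixels the caliper-style
corner measurement over-reads small diameters, on top of the formula's
ellipsoid idealization.

On ellipsoid lesions the Coniglobus estimate sits near 3/π ≈ 0.955 of the
voxel-count volume; on lobulated lesions its error grows sharply — the
package reproduces this shape bias on phantoms (see the methods vignette,
`vignettes/hemseg-methods.Rmd`).

A thin command-line wrapper is installed as `exec/ichseg` with
sub-commands `phantom`, `preprocess`, `train`, `predict`, `evaluate`,
`volume` and `report`.

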