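# mammoseg

Two-stage hybrid U-Net training and size-stratified evaluation for
mammographic lesion segmentation, exercisable end-to-end on synthetic
phantoms.

## The problem

Automated lesion segmentation in screening mammography fights two coupled
difficulties. First, lesions are a vanishing fraction of the pixels, so
plain cross-entropy training collapses toward "everything is background".
Second, clinical mammograms (4000–6000 px per side) must be downsampled to
network resolution (224 × 224), an 18–27-fold linear reduction under which a
250-pixel lesion retains only 0.3–0.8 equivalent pixels — small,
early-stage lesions are largely erased before the network ever sees them.

`mammoseg` implements, in R, a training protocol built for this setting and
the evaluation framework needed to expose its size-dependent behavior:

* **Synthetic phantom generator** — breast-shaped textured phantoms with
  irregular lesions of controlled pixel area and exact binary masks, so
  every downstream stage is testable without any clinical data.
* **Preprocessing** — [0, 1] normalization, CLAHE (clip limit 2.0, 8 × 8
  tiles), strict 0.5 mask binarization, bilinear resizing with mask
  re-binarization, lesion-preserving augmentation.
* **Patch sampling** — 224 × 224 lesion-centered positives with jitter,
  2:1 negatives under a strict <5 % mask-coverage bound, 80/20 split by
  source image, and a hybrid generator that substitutes lesion patches into
  full-image batches with probability 0.35.
* **U-Net** — encoder 64/128/256 (two 3 × 3 conv + BN + ReLU per block,
  2 × 2 max-pool, dropout 0.3), 512-filter bottleneck, transpose-conv
  decoder with skip concatenation, 1-channel sigmoid head. Layers,
  backpropagation and Adam are implemented natively (RcppArmadillo);
  gradients are verified against finite differences in the test suite.
* **Composite loss** — focal (γ = 2, α = 0.25) plus Tversky
  (α = 0.3, β = 0.7): `L = focal + tversky`.
* **Two-stage training** — Stage 1 patch pretraining; encoder + bottleneck
  weight transfer; Stage 2 full-image fine-tuning with hybrid substitution;
  Adam (default lr 1e-4), early stopping, LR decay and checkpointing on
  validation Dice.
* **Evaluation** — Dice, IoU, pixel accuracy, symmetric Hausdorff
  (undefined when either mask is empty), detection = IoU > 0.10 (strict),
  size strata small < 500 px / medium 500–1500 px / large > 1500 px,
  Kruskal–Wallis and Mann–Whitney group tests, size–quality correlations,
  and resolution-budget arithmetic.

## Worked example

The desk-scale study runs the entire protocol on 64 synthetic phantoms
(512-px native, downsampled to 224) with a reduced-width U-Net
(8/16/32 encoder, 64-filter bottleneck) — about ten minutes on one CPU:

```r
library(mammoseg)
study <- run_desk_study(seed = 1, verbose = TRUE)
attr(study$stage2$history, "best_val_dice")
#> [1] 0.5874
print(study$report)
```

```
Size-stratified report (n = 16, detected 16, missed 0)
 category  n n_detected n_missed detection_rate_pct mean_area
    small 10         10        0                100  278.4000
   medium  3          3        0                100  945.6667
    large  3          3        0                100 3709.3333
 mean_dice_detected mean_iou_detected
          0.5037541         0.3395788
          0.7641512         0.6191404
          0.7798915         0.6402135
Overall detection rate: 100.0%; missed share: 0.0%
Kruskal-Wallis Dice: H = 10.65, p = 0.004858
```

Reading the output: the fine-tuned network reaches a best validation Dice
of 0.587; every held-out lesion is detected under the lenient IoU > 0.10
rule, but segmentation *quality* is strongly size-dependent — mean Dice
among detected lesions climbs from 0.50 (small) to 0.78 (large), and the
Kruskal–Wallis test confirms the categories differ. That is the qualitative
signature of the resolution bottleneck this package exists to study.

The staged workbench offers the same pipeline as file-based commands
(`cmd_simulate`, `cmd_preprocess`, `cmd_pretrain`, `cmd_finetune`,
`cmd_evaluate`, `cmd_report`), with a CLI wrapper in
`inst/cli/mammoseg-workbench.R`:

```sh
Rscript inst/cli/mammoseg-workbench.R all --seed 1 --out runs/demo
```

## Method vignette

`vignettes/methods.Rmd` documents the model, the loss, the sampling and
evaluation conventions, the phantom design and its limitations, and every
numerical choice (tolerances, tie-breaks, degenerate inputs).
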