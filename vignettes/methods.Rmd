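---
title: "Two-stage hybrid U-Net training and size-stratified evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hybrid U-Net training and size-stratified evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammoseg)
```

## The problem

Screening mammograms are acquired at 4000-6000 pixels per side, while
convolutional segmentation networks typically ingest 224 x 224 inputs. A
breast lesion occupying a few hundred native pixels shrinks, after an
18-27-fold linear reduction, to well under one equivalent model pixel
(`resolution_analysis()` quantifies this). Segmentation of abnormal
mammograms is therefore dominated by two coupled difficulties: extreme
foreground/background class imbalance, and size-dependent information loss
that hits small (early-stage) lesions hardest. `mammoseg` implements a
training and evaluation protocol built around those two difficulties and
makes every stage testable at desk scale on synthetic phantoms.

## The pipeline

1. **Preprocessing** (`normalize_and_enhance()`, `resize_pair()`): images
   are converted to floating point, min-max normalized to [0, 1], and
   contrast-enhanced with CLAHE (clip limit 2.0, 8 x 8 tile grid - the
   conventional mammography setting and the package default). Masks are
   binarized with a *strict* threshold at 0.5; strictness keeps
   interpolation-induced exact-0.5 halos out of the lesion. Mask resampling
   is bilinear followed by re-binarization, so downstream code only ever
   sees {0, 1} masks. CLAHE runs through EBImage's implementation behind a
   padding wrapper (the underlying routine requires tile-divisible image
   sides); a flat field stays flat, and the output is clamped to [0, 1].

2. **Stage 1 - patch pretraining** (`build_patch_dataset()`,
   `pretrain_on_patches()`): 224 x 224 patches are cropped around lesion
   centroids with uniform jitter of up to 25% of the patch side per axis
   (clamped to the image). For each positive patch, two negatives are
   drawn by rejection sampling under a strict <5% mask-coverage bound, and
   by default restricted to windows with at least 50% breast foreground
   (an all-black background patch teaches nothing). The patch set is split
   80/20 *by source image* - never by patch - so validation patches can
   never share an image with training patches. Stochastic
   horizontal/vertical flips are applied during training.

3. **Encoder transfer and Stage 2 - hybrid fine-tuning**
   (`transfer_encoder()`, `finetune_full_images()`): all encoder and
   bottleneck parameters (including batch-norm running statistics) are
   copied into a fresh network of identical architecture; decoder and head
   start fresh. Fine-tuning then runs on full images resized to model
   resolution, except that each training sample is, independently with
   probability 0.35, replaced by a positive lesion patch. This hybrid
   substitution keeps small-lesion gradients present in the fine-tuning
   stream and prevents the encoder from forgetting Stage-1 lesion
   features. Validation uses full images only, because the monitored
   quantity is meant to estimate full-image segmentation performance.

## The network

`build_unet()` constructs a symmetric encoder-decoder with skip
connections: per encoder level two 3 x 3 convolutions, each followed by
batch normalization and ReLU, then 2 x 2 max-pooling and dropout
(rate 0.3); default widths 64/128/256 with a 512-filter bottleneck (also
two conv-BN-ReLU pairs, with dropout - applied there too, for symmetry,
and configurable); a decoder of 2 x 2 stride-2 transpose convolutions
concatenated with the matching encoder feature maps, two conv-BN-ReLU
pairs per level; and a 1-channel 1 x 1 sigmoid head. Weights are
He-uniform initialized from a seed, so builds are bit-reproducible.

There is no deep-learning framework behind this: the layers, the full
backpropagation and the Adam optimizer are implemented in the package
itself (RcppArmadillo kernels; im2col + BLAS GEMM convolutions, with the
input-gradient convolution expressed through the 180-degree-rotated
kernel to avoid scatter-adds). The test suite verifies the analytic
gradients of the entire network against central finite differences on a
micro configuration; conv biases that feed batch norm correctly receive
exactly zero gradient (the normalization removes them).

Two conventions to note: "dropout at each downsampling stage" is placed
after each encoder block's pooling; and batch-norm statistics are
computed over the whole mini-batch in training mode with running
statistics (momentum 0.1) used at inference.

## The loss

Training minimizes `mix_focal * focal + mix_tversky * tversky`:

* **Focal loss**: mean over pixels of `-alpha_t (1 - p_t)^gamma log p_t`,
  `p_t` the predicted probability of the true class. Defaults
  `gamma = 2`, `alpha = 0.25` (the standard focusing parameters).
  Probabilities are clipped at `1e-6` before the logarithm.
* **Tversky loss**: `1 - (TP + eps) / (TP + alpha FP + beta FN + eps)`
  with soft counts. Defaults `alpha = 0.3`, `beta = 0.7`, weighting
  missed lesion pixels more heavily than false activations - the
  sensitivity-oriented choice for sparse lesions. With
  `alpha = beta = 0.5` the term reduces exactly to soft Dice loss, which
  the tests exploit as an identity check.
* Mix weights default to (1, 1). All loss parameters are config-exposed;
  none of the published defaults for this protocol pin them down, so they
  are declared package defaults, not inferred constants.

## Evaluation framework

`evaluate_test_set()` emits one record per image: Dice, IoU, pixel
accuracy, symmetric Hausdorff distance (Euclidean, in model pixels;
*undefined* - not zero - whenever either mask is empty, and excluded from
aggregation), the lesion pixel area, and a detection flag: detected iff
IoU strictly exceeds 0.10. `stratify_records()` partitions records into
small (< 500 px), medium (500-1500 px, both boundary values inclusive)
and large (> 1500 px) categories and reports per-category counts,
detection rates, metric summaries among detected lesions,
Kruskal-Wallis tests (Dice and IoU across categories among detected),
a missed-versus-detected lesion-size comparison (Mann-Whitney two-sided,
with Welch's t as a secondary line), and Pearson size-quality
correlations among detected lesions (Spearman available). Rates are kept
at full precision internally; rounding to one decimal happens only in the
reporting layer.

The Kruskal-Wallis and Mann-Whitney statistics are computed by the
package's own rank-based implementations (tie-corrected H against a
chi-square reference; normal approximation with tie and continuity
correction), and the test suite requires them to agree with R's
`kruskal.test` and `wilcox.test(exact = FALSE)` to 1e-9 over randomized
instances - a deliberate dual-route design: the implementation is
exercised by the package, the reference implementation only ever acts as
an oracle.

Two conventions: Dice and IoU of two empty masks are defined as 1
(perfect agreement on absence; irrelevant for abnormal-only cohorts but
needed for robustness), and the lesion-area basis for stratification is
configurable between native-resolution and model-resolution pixel areas -
published size bands for full-resolution mammograms refer to native
areas, while the desk-scale study stratifies on the model grid.

## The phantom generator

`generate_phantom()` renders a half-elliptical breast-shaped foreground
(chest wall at the left edge) with multiscale smoothed-Gaussian texture,
and inserts lesions as irregular blobs whose boundary radius is modulated
by random low-order harmonics (orders 2-5, amplitudes up to 12%). The
realized mask area converges to within +/-15% of the target (usually
within 10%) via radius rescaling; the returned mask marks exactly the
rendered blob pixels, so ground truth is correct by construction.
Intensity-wise each lesion is a Gaussian-smoothed bump (sigma = r/4,
rendered in a padded window so the blur tail produces no seam) of
configurable contrast above local tissue.

`generate_cohort()` draws one lesion per image and apportions the
small/medium/large counts exactly by the largest-remainder rule; target
areas are sampled from category intervals shrunk by the rendering
tolerance, and realized areas are verified against the declared interval,
so every manifest row is category-consistent. Lesion contrast defaults
are graded by category (0.16 / 0.22 / 0.28): smaller lesions are fainter,
emulating the conspicuity gradient that real cohorts exhibit and giving
the desk-scale study a non-trivial detection problem.

Two calibration notes, decided while designing the phantom and then
frozen: texture amplitude is 0.03 with correlation length 1/12 of the
image side. An earlier, noisier texture (amplitude 0.06, 16-pixel
correlation length at any size) was visually indistinguishable from small
lesions after CLAHE - CLAHE amplifies whatever local variance exists -
and made the phantom task unlearnable at desk scale; the redesigned
texture is smoother than any lesion while still exercising low-contrast
boundaries. The phantoms make no claim of radiographic realism: there is
no pectoral muscle, no calcification clusters, no multi-view geometry,
and real parenchymal structure is far richer. Passing desk-scale tests
demonstrates that the *pipeline* behaves as specified, not that the
network would reach any particular performance on clinical data.

## The desk-scale study

`run_desk_study()` is the package's end-to-end reproduction at desk
scale, used by both the acceptance test and `scripts/acceptance.R`:
64 phantoms at 512-pixel native resolution (40 small / 16 medium /
8 large, category intervals expressed on the 224 model grid and scaled by
`(512/224)^2` to native areas), a 36/12/16 train/validation/test split,
the full two-stage protocol on a reduced U-Net (8/16/32 encoder filters,
64-filter bottleneck, identical topology), and size-stratified test
evaluation on the model-resolution area basis.

Sizing choices (all package choices, stated once): 15 epochs per stage
with early stopping (patience 10) and plateau learning-rate decay
(factor 0.5, patience 5); batch size 8; Stage 1 capped at 8 batches per
epoch; learning rate 5e-4 for both stages. The full-scale protocol's
default of 1e-4 remains the `train_config()` default, but a network two
orders of magnitude smaller, trained for a couple of hundred optimizer
steps, warrants a larger step size. Under seed 1 the study reaches a
Stage-2 best validation Dice around 0.59, detects lesions of every size
category, and reproduces the qualitative size gradient: detected-lesion
Dice rises from ~0.50 (small) to ~0.78 (large) with a significant
Kruskal-Wallis difference. These are properties of the synthetic study
conditions; they are recomputed, never asserted as constants.

## Numerical choices and degenerate inputs

* Batch norm: eps 1e-5, running-stat momentum 0.1; training-mode
  statistics over the whole batch.
* Loss smoothing: eps 1e-6 in the Tversky denominator and focal log
  clipping.
* Early stopping monitors validation Dice at binarization threshold 0.5;
  improvement must exceed 1e-9 (ties do not reset patience).
* A constant image entering normalization returns all zeros with a
  warning instead of dividing by zero.
* Negative-patch rejection sampling is bounded (100 attempts per patch);
  exhaustion returns fewer patches with a warning, never a mislabeled
  patch.
* An empty mask gives an explicit `NULL` from `lesion_bbox()` and an
  `NA` Hausdorff distance - sentinels, not exceptions.
* Apportionment ties (equal fractional remainders) break by category
  order, making cohort composition deterministic.

## Known limitations

* The native implementation is single-threaded and desk-scale; training
  the full 64/128/256/512 configuration on a real cohort is out of its
  intended range.
* Phantoms are deliberately simplified (see above); false-positive
  behavior on normal-tissue confounders cannot be studied with them,
  and the package makes no claim about clinical performance.
* The Mann-Whitney p-value uses the large-sample normal approximation
  (matching the reference implementation's non-exact path); for very
  small groups an exact test would differ.
* Multi-lesion images are supported by the generator but the evaluation
  framework scores one record per image, not per lesion.
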