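---
title: "Estimating tiller numbers from side-view images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tiller numbers from side-view images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A tiller is a basal shoot of a grass plant, and the number of tillers
per plant is a yield-determining phenotype.  Counting tillers by hand
is destructive and slow, so image-based estimation from a single
side-view photograph is attractive — but labeled images (with manually
counted tillers) are scarce, typically a few hundred, while unlabeled
images of the same plants number in the tens of thousands.  That
imbalance is the setting this package addresses: learn an image
representation from the *unlabeled* pool via self-supervised pretext
tasks, then estimate tiller counts from a *small* labeled set by
regression on the learned features.

`tillerest` implements the full chain:

1. **Synthetic scenes** (`generate_plant_spec()`, `render_scene()`) —
   a procedural generator of side-view potted-plant images with known
   tiller counts and pixel-exact ground-truth masks, so every later
   stage is testable without any external dataset.
2. **Normalization** (`build_template()`, `apply_template()`) — a
   pot-anchored geometric canonicalization to a 224 × 224 canvas.
3. **Segmentation and traits** (`segment_plant()`,
   `compute_traits()`) — colour-threshold plant segmentation and the
   two scalar traits used throughout: plant area $A_{sv}$ (pixels) and
   aspect ratio $HW$ (bounding-box height over width).
4. **Pretext training** (`make_task_spec()`, `train_backbone()`) — a
   convolutional backbone trained to predict a trait from the image,
   either as regression or as equal-frequency k-class classification.
5. **Feature regression** (`extract_features()`, `fit_svr()`,
   `fit_linear_head()`) — tiller-count estimation from headless
   backbone features by RBF support vector regression or a linear head
   trained with the backbone frozen.
6. **Baseline** (`estimate_fresh_weight()`, `estimate_tiller_count()`,
   `refit_*()`) — the conventional two-stage linear model
   $M_{fw} = a\,A_{sv} + b$, $TC = c\,M_{fw} + d\,HW + e$, with both
   the published and the re-estimated coefficient sets packaged, plus
   OLS refitting.
7. **Evaluation** (`cross_validate()`) — six-fold cross-validated mean
   absolute error with standard error and a 95% confidence interval.

## The synthetic generator: what it emulates and what it does not

The generator mimics the structural properties of laboratory side-view
phenotyping datasets: a pot of fixed physical size at the bottom of the
frame, a green branching plant rooted at the pot top whose projected
area and silhouette complexity grow with tiller count, a plain
near-white background, and several magnification groups (implemented
as integer zoom factors 1–3 by pixel replication, so pot pixel size
varies between groups exactly as camera zoom steps would cause).

Each plant is a fan of quadratic-Bézier tillers with short leaf
strokes.  Key defaults, chosen once:

* tiller count uniform on 1–12 (the range a labeled phenotyping set of
  this kind spans);
* per-tiller length lognormally jittered with σ = 0.25 around a
  per-plant height, so area carries a strong but imperfect count
  signal (Pearson r ≈ 0.89 at fixed magnification) — regression is
  learnable yet not trivial;
* plant colours are saturated greens (HSV hue 90°–122°, S 0.80–0.95),
  the pot a neutral grey, the background white with half-normal noise
  of sd 3/255 — this is what makes the stated saturation/Lab
  thresholds able to isolate the plant, mirroring the appearance
  assumptions of controlled-lab imagery;
* stroke widths 6 px (stems) and 5 px (leaves) at reference scale, so
  strokes survive the ~0.2–0.64× normalization rescale.

The generator does **not** emulate photorealistic texture, occlusion
between neighbouring plants, soil colour, shadows, specular highlights
or time-series growth.  Tests passing on these scenes therefore
demonstrate that the pipeline's machinery is correct and that the
method ordering (pretext features > random features, > linear
baseline) holds when its assumptions are met; they say nothing about
robustness to field imagery.

## Normalization

One template per magnification group records a crop rectangle, the pot
reference box, and the derived scale factor.  Pot *height* is the
anchored dimension: the image is rescaled so the pot is 32 px tall
(`pot_target`), because height is the pot dimension invariant under
side views; a config switch selects width instead.  The pot centre is
placed at the horizontal centre of the 224 × 224 canvas.  Vertical
placement is not uniquely determined by a centring rule alone, so the
pot top is anchored at 75% of the canvas height (plant above, pot
below) — a fixed, configurable choice made for reproducibility.
Resampling is one fused crop–scale–translate pass with bicubic
interpolation (Keys kernel, a = −0.75, channels clipped to [0, 1]) and
white padding.  Rectangles use 0-based half-open pixel coordinates
throughout.

## Segmentation and traits

The plant mask is the logical union of three 8-bit channel thresholds:
HSV saturation in [90, 255], Lab *a* in [0, 105] (green-ward), Lab *b*
in [150, 255] (yellow-ward); 8-connected components smaller than 10 px
are removed.  The union means any one firing channel claims a pixel,
so each interval is set conservatively.  These defaults were
calibrated on the synthetic scenes (they recover the generator's
ground-truth mask with IoU ≥ 0.94 across seeds and magnifications) and
are fully configurable — on real imagery they would be retuned, as any
workflow of this kind requires.

Aspect ratio is defined as bounding-box **height over width**.  This
reading is consistent with the negative aspect-ratio coefficient in
the packaged tiller-count baseline: at fixed biomass, taller-narrower
plants have fewer tillers.  All surviving components contribute to one
joint bounding box, since the traits describe "the plant", singular.
Both traits are flip-invariant (areas and box dimensions are preserved
by horizontal/vertical mirroring), which is exactly what licenses flip
augmentation in pretext training: augmented images keep their labels.

## Pretext tasks and backbone training

A pretext task predicts plant area or aspect ratio from the normalized
image.  Three modes exist: continuous regression (targets min–max
scaled to [0, 1]; raw pixel areas of order 10³–10⁴ would destabilize a
mean-squared-error loss), and 4- or 8-class equal-frequency
classification.  Equal-frequency bin edges are computed on the full
unlabeled pool before the train/test split (the pool, not the split,
defines the class structure); samples are stable-sorted by value and
dealt so every class holds ⌊n/k⌋ or ⌈n/k⌉ members, with ties allowed
to straddle adjacent bins.  New values are binned half-open, values on
an interior edge going to the higher bin.

Training follows the standard protocol: 80/20 split, mini-batch 128,
learning rate 10⁻⁴, 200 epochs, horizontal + vertical flips, and 12
independent restarts differing only in seed (weight initialization,
shuffling, augmentation draws), keeping the restart with the lowest
final *training* error; the held-out 20% is logged but never used for
selection.  Unstated-by-convention choices: softmax cross-entropy for
classification heads, MSE for the regression head, Adam as the
optimizer (the stated learning-rate magnitude is typical of Adam), and
He-normal initialization.

Two architectures are provided.  `"vgg16"` is the full-size 16-layer
network whose headless forward pass yields the 4096-d activation of
the second fully connected layer — the conventional feature tap when
the classifier head is purged.  Training it to convergence is a
GPU-scale undertaking; the package accepts externally supplied
pretrained weights through `load_backbone()` and never attempts to
reproduce large-scale pretraining itself.  `"tiny"` is a desk-scale
stand-alone architecture used by all tests: a 4× block-mean input
pooling (224 → 56 px), four 3 × 3 convolution blocks of 8/16/32/32
channels each followed by 2 × 2 max pooling, and one fully connected
feature layer of configurable width (default 64).  The training
engine — im2col + single-precision GEMM convolutions, explicit
backprop, Adam — is implemented in RcppArmadillo, runs single-threaded
deterministically, and produces bit-identical weights for identical
seeds.

## Tiller-count regression

Features come from the frozen, headless backbone in evaluation mode.
Two estimators are implemented:

* **SVR**: ε-insensitive support vector regression with an RBF kernel,
  C = 100 and ε = 1.0 by default.  The kernel width follows the
  "scale" rule γ = 1/(d · Var(features)); features are not
  re-standardized by default (a config switch enables z-scoring).  If
  every training residual fits inside the ε-tube the underlying solver
  returns no support vectors; the fit then degenerates to the constant
  mean predictor, which satisfies the same tube condition.
* **Linear head**: one affine map (feature_dim → 1) trained by
  mini-batch Adam under MSE with the backbone weights untouched
  (bit-identical before and after — the frozen-backbone contract is
  tested).  Linear regression is exactly a fully connected network
  without hidden layer, so the head is a single layer; an alternative
  with one hidden layer exists behind a flag-like config but is not
  the default, because a hidden layer would contradict that
  definition.  The head standardizes features internally (still one
  affine map end-to-end) and trains at learning rate 0.01 — the 10⁻⁴
  default is a fine-tuning rate for a pretrained deep network and
  cannot move a freshly initialized head to the target scale within
  200 epochs.

Estimates are kept continuous (unrounded); MAE is computed on the raw
estimates, with optional rounding only for reporting.

## The linear baseline

The conventional approach chains two affine models: fresh weight from
side-view area, then tiller count from fresh weight and aspect ratio.
The package ships the original published coefficients
($M_{fw} = 3.755\times10^{-5} A_{sv} - 0.2704$;
$TC = 0.22\,M_{fw} - 2.19\,HW + 5.26$) and the re-estimated set for
pot-anchored 224 × 224 normalized images
($M_{fw} = 0.005790\,A_{sv} - 0.3372$;
$TC = 0.1786\,M_{fw} - 1.1102\,HW + 3.885$).  The published area
coefficient refers to full-resolution pixels and does not transfer to
normalized images — which is exactly why the refit path exists.
Refitting is ordinary least squares with intercepts; R² is unadjusted
($1 - SS_{res}/SS_{tot}$).  Because the tiller-count stage is affine
in $M_{fw}$, its cross-validated predictions are invariant to which
affine area→fresh-weight proxy feeds it; the synthetic comparison
(where no fresh weights exist) exploits this and refits only the
tiller-count stage per training fold.

## Evaluation

Labeled samples are dealt round-robin from a seeded random permutation
into six folds (unstratified — nothing in the protocol calls for
stratification by count).  Each fold is held out once; fold MAEs are
averaged, and the spread statistics are defined across folds: SE =
sd(fold MAEs)/√k with the n−1 standard deviation, CI95 = mean ±
1.96·SE.  The regressor factory receives only training-fold data, and
any standardization happens inside the fold — a leakage guard that the
tests assert.  Prediction tables (measured vs estimated, with fold and
method) export to CSV, optionally with a scatter plot against the
identity diagonal.

## The scaled-down experiment

`run_tiller_experiment()` reproduces the method comparison at desk
scale: 2,000 unlabeled + 600 labeled synthetic scenes across three
magnification groups, area-regression pretext on the tiny backbone (20
epochs, 2 restarts, batch 64 at learning rate 10⁻³ — a from-scratch
schedule sized to the small pool; the full-protocol defaults remain on
`train_config()`), then six-fold CV of three estimators on the same
folds: a linear head on pretext features, the same head on
random-initialization features, and the refit linear baseline.  Scenes
stream through generation → normalization → segmentation in chunks, so
memory stays bounded.  On one CPU core a single seed takes about five
minutes.  Across seeds the expected ordering — pretext features beat
both random features and the baseline — is the package's acceptance
surface; it mirrors the qualitative claim that pretext training
improves estimation, not any particular MAE value, which at this scale
is not comparable to full-scale results.

## Numerical choices and degenerate inputs

* Bicubic kernel a = −0.75 with clamp-to-edge taps; outputs clipped to
  [0, 1]; binary masks are warped nearest-neighbour.
* Colour conversions use the 8-bit integer HSV and Lab conventions of
  mainstream image libraries (Lab a/b offset by 128, L scaled to
  0–255, D65 white); they are cross-checked against the base-R colour
  oracles to within rounding.
* Empty segmentations raise a typed error in `compute_traits()`; batch
  paths keep the row with NA traits and an `empty` flag so callers
  decide to drop or investigate.
* Equal-frequency binning requires at least k distinct values;
  constant regression targets are rejected.
* Restart selection is the exact argmin of logged final training
  errors; ties resolve to the earliest restart.
* `assign_folds()` requires n ≥ k ≥ 2; OLS refits reject
  zero-variance and collinear designs with singular-fit errors.

## Known limitations

* The synthetic scenes are deliberately simple; segmentation
  thresholds calibrated on them will not transfer to real imagery
  unchanged.
* The full-size architecture is provided for feature-shape fidelity
  and external weights; no attempt is made to train it at scale on a
  CPU.
* Magnification is emulated by integer pixel replication, not optical
  resampling; this preserves exact mask geometry at the cost of
  sub-pixel realism.
* The tiny backbone's 64-d feature space is far smaller than 4096-d;
  the scaled-down experiment demonstrates ordering, not attainable
  accuracy.
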