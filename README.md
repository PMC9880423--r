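# tillerest

Tiller-number estimation from single side-view RGB images of potted
grass plants, using self-supervised convolutional features.

A tiller is a basal shoot of a grass plant; the number of tillers per
plant is one of the main yield-determining phenotypes, and counting
them by hand is destructive and slow. Image-based counting is the
obvious alternative, but the labeled images needed to train a deep
network directly (plants with manually counted tillers) number only in
the hundreds, while unlabeled images of the same plants come in tens of
thousands. `tillerest` implements the semi-supervised recipe for that
situation:

1. **Pretext-task pretraining** — a convolutional backbone learns to
   predict an automatically computable trait of the plant (projected
   area *A*<sub>sv</sub> or bounding-box aspect ratio *HW*) from the
   image, using only unlabeled data. The trait can be predicted as a
   continuous target or discretized into 4 or 8 equal-frequency
   classes.
2. **Feature regression** — the trained backbone, with its head
   removed, maps each labeled image to a fixed-length feature vector;
   tiller counts are estimated from those features by RBF support
   vector regression (C = 100, ε = 1.0) or a linear head trained with
   the backbone frozen.
3. **Baseline** — the conventional two-stage linear model for
   comparison: fresh weight from area, then tillers from fresh weight
   and aspect ratio,

   *M*<sub>fw</sub> = a·*A*<sub>sv</sub> + b,  *TC* =
   c·*M*<sub>fw</sub> + d·*HW* + e,

   with both the published and the re-estimated coefficient sets
   packaged, plus OLS refitting.
4. **Evaluation** — six-fold cross-validated mean absolute error with
   standard error and 95% confidence interval, and export of
   measured-vs-estimated tables.

Everything upstream of the learning (pot-anchored normalization to a
224×224 canvas with a 32-px pot, HSV/Lab colour-threshold plant
segmentation with logical-union semantics, trait computation) is
implemented and tested too, and a procedural generator of synthetic
potted-plant scenes with pixel-exact ground-truth masks makes the whole
pipeline testable without any external dataset. The CNN training
engine (im2col/GEMM convolutions, Adam, restarts) is single-precision
RcppArmadillo code that runs deterministically on one CPU core.

## Worked example

```r
library(tillerest)

# a synthetic scene with known ground truth
spec  <- generate_plant_spec(seed = 7, tiller_range = c(1, 12),
                             magnification_group = 2)
scene <- render_scene(spec)
scene$tiller_count
#> [1] 10

# pot-anchored normalization: the 100-px pot is scaled to 32 px
template <- template_from_scene(scene)
template$scale_factor
#> [1] 0.32

img    <- apply_template(scene$image, template)   # 224 x 224 x 3
mask   <- segment_plant(img)
traits <- compute_traits(mask)
c(traits$area, traits$aspect_ratio)
#> [1] 4397.000    1.246

# conventional linear baseline with the packaged refit coefficients
co <- baseline_coefficients("refit")
fw <- estimate_fresh_weight(traits$area, co)
estimate_tiller_count(fw, traits$aspect_ratio, co)
#> [1] 6.988
```

The area (4,397 normalized pixels) feeds the fresh-weight model
(25.1 g estimated), which together with the aspect ratio gives a
baseline estimate of 7.0 tillers against a true count of 10 — typical
of the baseline's behaviour on large plants, and the gap the learned
features close.

The full scaled-down comparison (2,000 unlabeled + 600 labeled scenes,
tiny backbone, area-regression pretext, six-fold CV) runs in about
five minutes on one core:

```r
res <- run_tiller_experiment(seed = 1)
res$mae
#>  pretext   random baseline
#> 1.018910 1.355691 1.285211
```

Features from the pretext-trained backbone estimate tiller counts with
lower cross-validated MAE than features from the same architecture
with random weights, and than the refit linear baseline.

A thin command-line wrapper over the same functions lives at
`inst/cli/tiller.R` (subcommands `generate`, `normalize`, `segment`,
`pretrain`, `extract`, `fit`, `baseline`, `evaluate`, `run-all`, each
reading one YAML config).

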