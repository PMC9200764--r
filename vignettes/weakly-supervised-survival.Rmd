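---
title: "Weakly supervised survival prediction from H&E tiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised survival prediction from H&E tiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prognostic models built from haematoxylin-and-eosin (H&E) stained tissue
sections usually require pathologists to outline the regions that matter.
`histrisk` implements the alternative: train a convolutional risk predictor
on small tiles cut from whole-slide images using *only* the patient-level
outcome — the right-censored overall-survival time and its event indicator.
No tile ever carries its own label; the weak supervision flows entirely
through the ranking structure of the Cox partial likelihood. A model trained
this way emits one hazard-ordered risk score per tile, the patient's risk is
the median of their tile risks, and a risk density map rendered from the
tile scores shows *where* on the slide the model sees elevated risk.

## The model

### Cox partial-likelihood loss

Given risks $r_m$ for the patients in a mini-batch with times $t_m$ and
event indicators $\delta_m$, the training loss is the negative log partial
likelihood

$$\ell = -\sum_{m:\,\delta_m = 1}\Big(r_m - \log\!\!\sum_{j:\,t_j \ge t_m}\!\! e^{r_j}\Big),$$

computed with max-subtraction for numerical stability (`cox_nll()`). The
risk set is the mini-batch itself, which is why batches must contain at most
one tile per patient (`make_minibatches()`): repeated patients would place a
patient in their own risk set several times and bias the denominator. A
batch with no observed event contributes an empty sum and is skipped; a
leftover batch survives only with at least two patients and one event. Tied
event times use the Breslow approximation (shared risk set), the form the
loss above reduces to; Efron's correction is available via `ties = "efron"`.
Both the value and the analytic gradient are verified in the test suite
against the `survival` package and central finite differences.

### Backbone and attention

The risk network (`risk_model()`) is a compact convolutional stack: 3x3
convolutions with ReLU and 2x2 max-pooling (channels 8-16-32 for the default
`tiny` backbone, 64 px input, ~6.6k parameters), attention gating of the
final feature map, global average pooling, one hidden dense layer and a
single linear risk output. Forward and backward passes are written in
vectorised R over BLAS matrix products (im2col convolutions, transposed-
convolution input gradients); an exhaustive finite-difference check of every
parameter and of the input gradient is part of the tests. Large pretrained
ImageNet backbones are deliberately not bundled: the scientific content —
weak supervision, the loss, the attention gating, the evaluation protocol —
is independent of backbone capacity, and a desk-scale CPU backbone keeps the
whole pipeline testable. Requesting `resnet18` & co. raises an informative
error; `backbone = "custom"` exposes the channel widths.

Attention gating (`attention_fuse()`) refines a feature map
$F \in \mathbb{R}^{H\times W\times D}$ by element-wise sums of two gated
branches: channel gates $\sigma(\text{spatial mean of } F_{\cdot\cdot d})$
and spatial gates $\sigma(\text{channel mean of } F_{hw\cdot})$, each
multiplied into $F$ by a Hadamard product with broadcasting. The default
gating is deliberately parameter-free, so toggling `attention_enabled` never
changes the parameter count — the ablation is a pure architecture switch.
Phrasings of such gates that pass the features through a learnable 1x1
projection conflict with a parameter-free reading; we honour the
parameter-free variant by default and expose the learnable projection behind
`attention_learnable = TRUE` for experimentation.

The gate is inserted after the last convolutional block, before global
pooling — the stage where spatial resolution is coarse enough for the
spatial gate to express region relevance but not yet collapsed.

### Training protocol

`train_config()` defaults: AdaGrad-style per-parameter accumulators combined
with heavy-ball momentum 0.95, initial learning rate $10^{-4}$ decayed by
0.97 per epoch, weights initialised $\mathcal{N}(0, 0.01^2)$ with zero
biases, unique-patient mini-batches of 8, and per-tile augmentation each
epoch (flips, right-angle rotations, hue shifts within $\pm 0.05$, crops of
at least 80% area resized back, random erasing of 2-20% of the area with
uniform noise). "AdaGrad with momentum" is not textbook AdaGrad; we read it
as the adaptive accumulator plus a heavy-ball velocity, and plain AdaGrad
and SGD-with-momentum remain available through `optimizer`. The decay is
applied per epoch. Augmentation magnitudes (hue width, erase fractions,
minimum crop area) are label-preserving choices exposed as arguments, since
tile-level labels do not exist to calibrate them against.

One practical property worth knowing: with $\mathcal{N}(0, 0.01^2)$
initialisation the risk output starts at a tiny scale and the *value* of the
batch partial likelihood is initially dominated by batch composition rather
than by the risks. Because the adaptive optimizer's step size is invariant
to gradient scale, ranking signal nevertheless emerges within a few hundred
steps; the loss value follows later. Short smoke runs should therefore
assert ranking (c-index), not loss magnitude — the suite's loss-decrease
check uses a separable toy problem and the full-scale check runs at the
study conditions below.

## Tiling

Tissue is segmented by Otsu's method on a 256-bin grayscale histogram;
tissue is everything *darker* than the threshold, because H&E tissue is
darker than glass. Tiles are enumerated on a raster grid of half-open
`size x size` boxes (0-based, x rightward, y downward) with a default
stride of half the tile size — 50% maximum overlap — and a box is kept when
at least half of it is tissue (`min_tissue = 0.5`; the threshold is exposed
because no principled value exists without annotations). Tile sampling
without replacement falls back to keep-all-plus-top-up with replacement when
more tiles are requested than exist, so small slides still yield a full
pool. Working magnifications below the source resolution are emulated by
average-pooling (`downsample` in `open_slide()`); pyramidal formats can be
plugged in through the `slide_reader` contract (`dims`, `read_region`,
`thumbnail`).

## The synthetic cohort generator

`generate_slide()` emulates what the pipeline needs from H&E, not histology
itself: a pink stroma field with low-frequency texture, a near-white glass
margin (so Otsu has a real segmentation task), and dark-purple elliptical
nuclei placed by an inhomogeneous Poisson process whose smooth intensity
field fluctuates around the slide's base density. The per-pixel ground truth
("informativeness") is that intensity field scaled onto [0, 1] by a fixed
cohort-level reference (twice the upper end of `nuclei_density_range`)
rather than per-slide extremes — per-slide min-max scaling would erase the
between-slide ordering that drives survival. Colour tones are chosen so the
tissue-glass grayscale separation dominates the histogram, as it does on
real low-magnification thumbnails; with nuclei too dark and stroma too
light, Otsu would latch onto the nuclei instead.

`generate_cohort()` draws per-patient densities uniformly from
`nuclei_density_range` (default 5-40 nuclei per 100x100 px), takes the
slide-mean informativeness as the patient feature, standardises it to $z$,
and draws event times from the proportional-hazards model
$h(t \mid z) = h_0 \, e^{\beta z}$ with constant baseline $h_0$ (exponential
times; a Weibull shape is available). Censoring times are uniform on
$(0, q)$ with $q$ solved numerically so the expected censored fraction
matches `censor_rate`; the generator reproduces cohort censoring levels from
roughly 30% to 60% within sampling error. Defaults (40 patients,
$\beta = 1.5$, 30% censoring, $h_0 = 0.02$/month i.e. median survival around
three years at $z = 0$) are the desk-scale study conditions used throughout
the tests. `render_slides = FALSE` skips image synthesis and uses the density
itself as the feature, for large cohorts where only the survival law matters.

What the generator does *not* emulate: stain variation between scanners,
tissue-type heterogeneity, pen marks, blur, nuclear pleomorphism. Passing
tests therefore demonstrate that the machinery — weak supervision through
the Cox loss, tiling, aggregation, evaluation — works when the image signal
is real but simple; they say nothing about histological realism.

## Evaluation

* `concordance_index()` implements Harrell's c-index with the standard
  comparable-pair rule under right censoring: a pair is comparable when the
  shorter time is an observed event and the times differ; tied risks score
  0.5. It is checked against brute-force pair enumeration and the
  `survival` package.
* `stratify_median()` splits at the cohort median (ties to "low", making the
  split deterministic), the threshold being computed over pooled
  cross-validated risks.
* `km_estimate()`, `logrank_test()` and `cox_regression()` wrap the
  `survival` package (product-limit estimator, two-group log-rank with the
  O/E hazard-ratio estimate, Newton-Raphson Cox fits with Breslow ties and
  Wald 95% intervals); these are standard statistics, not this package's
  contribution, and the wrappers only fix conventions (two-sided p-values,
  per-covariate univariable mode, c-index of the linear predictor, monotone
  likelihoods flagged as non-converged). No multiple-testing correction is
  applied; p-values are reported raw.
* `crossval_cindex()` evaluates out-of-fold risks **within** each fold and
  averages. Cox risks are only identified up to monotone transforms, so
  risks from different fold models are incommensurable; pooling them into
  one ranking silently corrupts the c-index (cross-fold pairs are then
  ordered by arbitrary scale offsets rather than by learned risk). Pooled
  risks remain appropriate for the median-threshold stratification, which
  only needs a cut point.

## Numerical choices and degenerate inputs

* Log-sum-exp in the Cox loss is stabilised by subtracting the max risk;
  shift invariance holds to 1e-9 and is asserted.
* Otsu on a constant image raises a "degenerate histogram" error rather than
  inventing a threshold.
* All-equal risks: `render_risk_map()` paints a uniform mid-scale map;
  `stratify_median()` labels everyone "low" with a warning.
* Max-pooling ties resolve to the first quadrant in raster order; gradients
  flow to exactly one argmax per window.
* Day-to-month conversion uses 30.44 (mean Gregorian month).
* Every stochastic step (splits, sampling, augmentation, initialisation,
  batching, generation) takes an explicit seed and restores the caller's RNG
  state, so runs are bit-reproducible.

## Problem sizes used by the test suite

The end-to-end checks run 5-fold patient-level cross-validation (70/10/20
train/validation/test by fold construction) on 40 synthetic patients with 30
tiles of 64x64 px each, 10 epochs per fold, for both the signal
($\beta = 1.5$) and null ($\beta = 0$) conditions; parameter-recovery checks
use 400-patient cohorts over three seeds; the c-index oracle equivalence
sweeps 100 random instances up to n = 200. These sizes were chosen so the
full pipeline — generation, tiling, training, scoring, statistics — runs on
one CPU core at desk scale while leaving enough statistical resolution for
the boundary checks to be meaningful.

## Known limitations

* The bundled backbone is deliberately small; absolute discrimination on
  real WSIs would need a larger backbone and a real slide reader behind the
  `slide_reader` contract.
* Stain normalisation, artifact detection and multi-resolution context are
  out of scope.
* The spatial attention map is not returned as an explanation object; risk
  density maps (tile-level) are the interpretability surface.
* Patient-level splitting is unstratified; with very small cohorts a fold
  can lack comparable pairs, in which case its validation c-index is
  reported as `NA` and the fold is dropped from averages.
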