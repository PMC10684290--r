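---
title: "Semi-supervised berry counting by density mutual exclusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised berry counting by density mutual exclusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrycount)
```

## The counting model

Counting densely clustered fruit from bounding boxes fails when objects
occlude each other; the density-map formulation sidesteps detection
entirely. Each object is annotated by a single center point, and the
ground-truth label for an image is a density map

$$D(x) = \sum_{n=1}^{N} G_\sigma(x - x_n),$$

a sum of unit-integral isotropic Gaussian bumps ($\sigma$ fixed, default 15
pixels) centered on the $N$ annotation points. The sum of the map equals the
object count, so a network that regresses $D$ counts by integration:
`count_from_density()` is literally `sum()`. Bumps are evaluated on a fixed
window of half-width $4\sigma$ and truncated at the image border without
renormalization; for points at least $4\sigma$ from every border the count
is conserved to better than 1% (`make_density_map()` tests assert this).

The regressor is a VGG-style convolutional trunk: four stages emitting
feature maps at 1/2, 1/4, 1/8, 1/8 of input resolution (64, 128, 256, 512
channels at full width), then two 3×3 dilated-convolution stages (rate 2,
padding 2, 512 and 256 channels) that enlarge the receptive field without
further downsampling. All outputs live on the H/8 × W/8 grid; ground truth
is brought there by sum-preserving 8×8 block summation
(`downsample_sum()`), chosen over interpolation because count preservation
is the invariant that matters. A `width_scale` multiplier shrinks every
stage proportionally — the "tiny" 1/16-width variant used throughout the
tests keeps the exact topology (verified by a layer census) at ~20k
parameters, small enough for CPU training.

## Density levels and the auxiliary tasks

The semi-supervised mechanism rests on *density levels*. All strictly
positive values of the labeled ground-truth maps (at network resolution)
are pooled and sorted ascending into a sequence of length $T$; the
threshold at quantile position $S$ is the value at 1-based index
$\mathrm{clamp}(\lceil S\,T\rceil, 1, T)$. The default positions
$\{0, 0.33, 0.66, 1\}$ yield four thresholds bounding $k = 3$ levels
(3 was the best-performing predictor count in the source study's ablation;
the mutual-exclusion rule needs at least 2). Level $j$ is the half-open
interval $(\ell_j, t_{j+1}]$ with $\ell_1 = 0$ and $\ell_j = t_j$
otherwise: the lowest interval opens at zero rather than at the smallest
nonzero value so that no nonzero pixel is orphaned, and ties on the upper
bound resolve to the lower level. Each of the $k$ auxiliary heads is a 1×1
convolution plus sigmoid that segments its level's pixels.

Unlabeled images train only these auxiliary heads. Per pixel, a head
"fires" when its probability strictly exceeds the confidence $t_p = 0.8$:

* exactly one head fires — the pixel becomes that level's foreground
  (and, implicitly, the other $k-1$ heads' background);
* two or more fire — the predictions contradict the prior that a density
  value belongs to exactly one level, and the pixel is excluded from
  supervision;
* none fires — the pixel is excluded as unconfident.

The zero-fire case is the one genuinely open design choice here. We first
implemented the alternative — treat unconfident pixels as valid
all-background supervision — and found it self-defeating at desk scale:
with unlabeled images outnumbering labeled ones 9:1, the all-background
gradient keeps every head's probability below $t_p$ indefinitely, so no
pixel ever fires and the mutual-exclusion correction never runs — the
level heads end up *less* confident than in a labels-only run.
Excluding unconfident pixels is also the standard convention in
confidence-thresholded pseudo-labeling; the background-supervision variant
remains available as `pseudo_label_config(exclude_unconfident = FALSE)`.

## Losses

Writing $M'_i$ for the predicted level-probability maps and $M_i$ for the
binary targets (ground truth on labeled images, corrected pseudo-labels on
unlabeled ones):

* **Cross-entropy** — standard per-pixel binary cross-entropy
  $-[M \log M' + (1-M)\log(1-M')]$, masked by the validity map and averaged
  over valid pixel–level pairs, with probabilities clipped to
  $[\varepsilon, 1-\varepsilon]$. (The per-pixel average is a choice: the
  compact printed form of this loss in the source method averages only over
  the $k$ predictors and leaves pixel normalization implicit.)
* **Density difference** — columns $f'_{i,w}$ of each predicted map and
  $f_{j,w}$ of each target map are compared by $\varepsilon$-stabilized
  cosine similarity $S$. $L_{max} = -\frac1k\sum_i\sum_w S(f'_{i,w},
  f_{i,w})$ pulls each map toward its own target;
  $L_{min} = \frac{1}{k(k-1)}\sum_i\sum_{j\ne i}\sum_w S(f'_{i,w}, f_{j,w})$
  pushes it from the other levels'. The sums over columns are deliberately
  not normalized by width, following the method's stated form, so the loss
  scales with map width. Invalid pixels are zeroed in pseudo-label target
  columns first. The $\varepsilon$ sits in the denominator rather than a
  zero-vector branch to keep the expression differentiable; all-zero
  columns contribute similarity 0.
* **Density MSE** — squared L2 norm of the per-pixel difference, summed
  over pixels (batch size 1).

The composite objective is $L_{MSE} + \lambda_1 L_{CE} + \lambda_2 L_{DD}$
on labeled images and $\lambda_3 L_{CE} + \lambda_4 L_{DD}$ on unlabeled
ones, with $(\lambda_1,\ldots,\lambda_4) = (0.01, 1, 0.01, 1)$. The absence
of a density term on unlabeled images is the routing that shields the
regressor from pseudo-label noise; `train()` enforces it and a numeric test
confirms the density head's gradient is identically zero on unlabeled
steps.

All gradients are hand-derived (the convolution, pooling and loss adjoints
live in compiled kernels) and validated against central finite differences
at tolerance 1e-4 in the test suite.

## Training protocol

The published protocol is the default `train_config()`: batch size 1, Adam
with library-default moments, initial learning rate 1e-6 halved every 30
epochs, 120 epochs, random crops of 1296 × 864 and random horizontal flips
(vertical flips would be unnatural for vineyard rows). Each epoch is one
uniformly shuffled pass over the union of labeled and unlabeled images;
pseudo-labels are regenerated at every unlabeled step from the model's
current predictions, with no persistence or momentum. Per-epoch validation
MAE is tracked and the best-MAE parameters retained. Two runs with the same
seed and configuration are bit-identical.

## The synthetic scene generator

Because the field dataset cannot ship with the package, every stage is
exercised on seeded synthetic scenes (`generate_scene()`): a
Thomas-process-like layout — cluster centers uniform in frame, berries
Gaussian-scattered around them with per-cluster spread drawn from a range —
rendered as shaded, occluding disks on a smoothly textured background, with
the disk centers as annotations and rejection resampling into a target
count range. The defaults (256 × 256, 30–200 berries) are a scaled-down
analogue of field images whose counts span roughly 206–1585. The generator
reproduces the statistical preconditions the method relies on — tight
clusters, several density levels (a test asserts all three levels are
populated on ≥ 90% of generated labeled images), occlusion — but not the
photometric variability of real vineyards: cultivar differences, lighting,
motion blur, leaf backgrounds. Green-field tests therefore validate the
machinery and the direction of effects, not field-scale error magnitudes.

## Problem sizes and the toy benefit experiment

Desk-scale parameters used by the tests and the acceptance script, chosen
once as realistic CPU-scale analogues: tiny network (`width_scale = 1/16`),
scenes of 128 × 128 with 8–50 berries for training experiments (quarter
area of the default scene, counts scaled accordingly), $\sigma = 4$ matched
to the 2–4-pixel synthetic berry radius, Adam at 1e-3 for the tiny network
(the published 1e-6 is tuned to a full-width backbone), 30 epochs.

`semi_supervised_benefit()` is the directional analogue of the labels-only
ablation: 40 training images at 10% labeled, identical initialization for
both arms, best validation MAE compared on 8 held-out images over 3 seeds
(the acceptance script reports the per-arm means and the win fraction).
On this synthetic task the two arms tend to land close to each other: four
labeled synthetic images already cover the low-variability scene
distribution, so unlabeled data has little headroom to help, unlike the
field regime where the labels-only baseline degrades severely. The
experiment honestly reports whichever way each seed falls; it should be
read as a check that the semi-supervised pathway functions and does no
harm, not as a reproduction of the published margins, which would require
GPU-scale training on the real imagery.

## Numerical and degenerate-case choices

* Quantile index is 1-based `ceiling(S*T)` clamped to `[1, T]`; $S = 0$
  maps to the smallest nonzero value.
* Pixels above the top threshold (possible only for maps outside the
  labeled pool) and exact zeros are background on all level maps.
* A probability exactly equal to $t_p$ does not fire (strict inequality).
* Cross-entropy with zero valid pixels returns 0 with a warning rather
  than dividing by zero; inside the training loop this situation is
  routine early on and the warning is suppressed there.
* Inputs not divisible by 8 are right/bottom zero-padded and the outputs
  kept at the padded grid; annotation coordinates are 0-based
  pixel-center, and a horizontal flip maps $x \mapsto W - 1 - x$ with
  fractional coordinates in $(W-1, W)$ clamped to 0.
* Max-pooling resolves ties to the first element scanned, keeping runs
  bit-reproducible.
* Predicted counts are raw density sums; `clip_negative` optionally zeroes
  negative pixels for sensitivity analysis.

## Known limitations

* The hand-written network trains on one CPU core; it is meant for
  desk-scale experiments and method study, not production inference on
  full-resolution field imagery.
* Pretrained backbone weights are a loading hook only; no weights ship
  with the package, so field-scale accuracy claims are out of scope.
* The synthetic generator does not model cultivar appearance, lighting
  variation, or non-berry distractors; conclusions about real-world
  robustness require real data.
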