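---
title: "Estimating nutrient composition from food images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nutrient composition from food images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a single photograph of a dish, nutrinet estimates the fractions of
protein, fat, fiber, carbohydrate, minerals and water it contains, plus an
explicit *remainder* class. Published composition tables report nutrients as
percentages of a reference intake (NRV%) that do not sum to 100%, so the
remainder class is what lets a softmax simplex represent a table row
faithfully: every prediction and every reference vector in this package lives
on the unit simplex, and NRV%-style output is just the fraction times 100.

Two things make the problem harder than ordinary image classification: the
dish occupies an unknown part of a cluttered scene, and the mapping from
appearance to composition is what must be learned, not a class label. The
architecture therefore splits into four stages, each implemented and tested
separately and composed by `model_forward()`.

## Stage 1: environment feature extraction (EFE)

The front end is designed to damp background ("environment") information
before any semantics are extracted.

**HSI conversion.** The image is converted from RGB to hue–saturation–
intensity through the chromaticity form: with $r = R/(R{+}G{+}B)$ and
likewise $g, b$,

$$h = \cos^{-1}\!\frac{0.5\,[(r-g)+(r-b)]}{\sqrt{(r-g)^2+(r-b)(g-b)}},$$

taking $h$ itself when $b \le g$ and $2\pi - h$ when $b > g$;
$s = 1-3\min(r,g,b)$, $i = (R{+}G{+}B)/(3\cdot255)$, then
$H = h \cdot 180/\pi \in [0,360)$, $S = 100\,s$, $I = 255\,i$. Degenerate
pixels are handled by convention: achromatic pixels ($R=G=B$) take $H = 0$
(their $S = 0$ already marks them), pure black maps to $(0,0,0)$, the arccos
argument is clamped to $[-1,1]$, and the squared denominator is floored at
$10^{-24}$ so the conversion is exact away from degeneracy but finite
everywhere. Before entering the network the three planes are rescaled to
$[0,1]$ by their ranges (360, 100, 255) so no channel dominates the linear
embedding. A configuration switch (`hsi_mode`) chooses between replacing RGB
with HSI (the default) or concatenating both; replacement is the default
because the HSI planes carry the same information with the dish/background
contrast made more explicit.

**Working grid.** After conversion the image is block-mean pooled to a
`grid x grid` token lattice (default 8 x 8). Attention over raw 224 x 224
pixel grids is quadratic in fifty thousand tokens; pooling to a coarse
lattice is the package's choice for making the dual-attention encoder
tractable while keeping the architecture intact. The grid is configurable.

**Multi-scale convolutions and MDN.** A pointwise linear layer embeds the
pooled HSI planes (reading "mapping the image to one dimension through linear
layers" as a per-pixel projection — a literal flatten would destroy the
spatial structure the convolutions need), then parallel same-padding
convolutions with kernel sizes {1, 3, 5, 7} capture several spatial scales;
their outputs are concatenated and recombined by a 1 x 1 convolution. The
distribution-partition normalisation (MDN) then groups feature *planes* by
the similarity of their value histograms under the KL divergence
$KL(P\|Q)=\sum_x P(x)\ln(P(x)/Q(x))$ and divides each group by the Euclidean
norm of all of its elements, before a final 1 x 1 convolution.

MDN needed several concrete decisions:

* **Partition unit.** Planes (channels), not pixels: the norm division stays
  smooth and channel granularity keeps the layer cheap. The plane-to-group
  routing is recomputed on every forward pass and treated as
  non-differentiable; gradients flow through the norm division itself
  (including the $-x\,(g\cdot x)/\|x\|^3$ term).
* **References.** With the default $K = 2$ the two reference histograms are
  those of the planes with the highest and lowest mean absolute activation —
  a proxy for the subject/background contrast the layer is meant to exploit.
  For $K > 2$, medoids are seeded at evenly spaced activation ranks and
  refined by a deterministic k-medoids sweep under KL.
* **Histogram range.** `plane_histogram()` spans each plane's own min–max
  (its documented contract), but the partitioning step bins all planes over
  the tensor-global range: per-plane ranges would make a constant-0 plane
  and a constant-1 plane indistinguishable, which is exactly the contrast
  the layer must see. Histograms use 32 bins with $10^{-8}$ additive
  smoothing so divergences stay finite on disjoint supports; assignment ties
  break toward the lower partition index.
* **Norm scope.** The divisor is the norm over the whole partition's
  elements (not per plane), so each nonzero partition leaves with unit
  Euclidean norm — the property the tests assert, together with idempotence
  and per-partition scale invariance.

## Stage 2: dual-attention encoder

Tokens are the flattened grid cells. Each of the $L$ encoder layers projects
the token matrix $X$ seven ways — $Q = W_q X$, $K$, $V$ and separately
parameterised global $Q_g, K_g, V_g$, plus the output map $W_o$ — and runs
two parallel scaled dot-product attentions,
$C = \mathrm{softmax}(QK^T/\sqrt{d_k})\,V$ ("focused") and the structurally
identical $I$ on the global triple ("independent"), fused as
$W_o(\alpha C + \beta I)$. The fusion scalars $\alpha, \beta$ are trainable,
initialised at 0.5 each (trainable subsumes fixed). Multiple heads are
implemented as the standard width-splitting replication of the C/I
machinery with $d_k = d/n_\text{heads}$; `n_heads = 1` reproduces the
printed single-head formulas exactly. A GELU feed-forward sublayer of width
$4d$ follows each attention block, both wrapped in additive residuals; no
layer normalisation is inserted in the encoder because the printed formulas
carry none and the networks trained here are shallow enough not to need it.

The stack ends with atrous spatial pyramid pooling — a 1 x 1 branch plus
3 x 3 dilated convolutions at rates {1, 2, 4} by default on the 8 x 8 grid
(the classic {6, 12, 18} rates are available but larger than a coarse
lattice can use meaningfully) — and a residual path from the original image:
the RGB input is pooled to the encoder grid and 1 x 1-projected to the
feature width, then added. That is the package's mechanism for the
stated image-to-encoder residual, which leaves the dimension matching
unspecified.

## Stage 3: token-sleeping decoder

The decoder attends over the encoder tokens with a supervised attention
head. During training a supervision layer tracks each token's running mean
absolute post-attention activation over a window (default 50 steps). A token
whose statistic falls strictly below a threshold `tau` (default $10^{-3}$)
is put to sleep for `sleep_epochs` (default 2) epochs: its current
activation is frozen, it is excluded from the attention matmul, and it is
not re-armed while asleep; counters decrement at epoch boundaries and the
token wakes at zero. One guard exists beyond the stated rules: the most
active awake token is never allowed to sleep, because attention over an
empty token set is undefined. Sleeping is a training-time mechanism; at
evaluation every token participates. The supervision statistics are
"neuron" activity read at token granularity — the mechanism's own framing
shifts from neurons to tokens, and token granularity is what shrinks the
attention matmul.

After attention come dropout (train only), layer normalisation, a residual
stack of GELU fully connected layers, mean pooling over the awake tokens,
and a final linear map to the decoder feature vector (width 64 in the
reference configuration).

## Stage 4: nutrient head, objective, metrics

The head is two fully connected layers with a GELU hidden activation,
train-only dropout, and a softmax, so the output is always a distribution
over the nutrient classes. GELU is computed as $x\,\Phi(x)$ with the exact
erf-based normal CDF, not the tanh approximation. Training minimises the
weighted mean absolute error

$$\mathrm{WMAE} = \frac{1}{\sum_i w_i}\sum_i w_i\,\lvert y^{pred}_i - y^{true}_i\rvert,$$

with uniform weights by default (no canonical importance weighting exists;
the vector is fully configurable). The $\lvert\cdot\rvert$ subgradient at 0
is taken as 0. Optimisation is Adam (lr $10^{-3}$, batch 25 by default) with
analytic backpropagation through every stage, verified against central
finite differences in the test suite.

Evaluation uses the regression-style accuracies: with $X_p$ the content of
the class with the largest predicted probability and $X_r$ its reference
value, $\mathrm{Top1} = \max(0,\ 1 - \lvert X_p - X_r\rvert/X_r)$, and Top-5
averages the same clamped score over the five most probable classes. The
clamp is forced by the zero-score rule — without it, overshooting past
$2X_r$ would yield negative "accuracy". Background stability is the
population variance of the predictions for one foreground across background
variants, per nutrient class; population rather than sample variance because
the quantity describes exactly the rendered set, not a sample from a larger
one.

## The synthetic food universe

All training and evaluation in this package runs on generated images: six
foods, each an elliptical dish whose hue and sinusoidal texture frequency
encode its nutrient vector by a linear rule published in
`synthetic_spec()` (carbohydrate rises with hue, protein with texture
frequency, fat with the food index; fiber and minerals cycle at small
positive levels; water is constant at 0.25; the remainder absorbs the rest —
every entry strictly positive so the top-5 metric is defined everywhere, and
the food-to-nutrient map injective so the task is identifiable). Dishes are
rendered at 64 x 64 with seeded position/size jitter and composited over
four background styles (solid, gradient, checker, noise). The foreground is
a deterministic function of (food, seed) only, never of the background — so
same-foreground/different-background pairs are exact by construction, which
is what the stability ablation needs.

What the generator does *not* emulate: photographic noise, lighting,
occlusion, mixed dishes, perspective, or any real correspondence between
appearance and composition. Passing the recovery tests therefore shows that
the implementation can learn an appearance-to-composition mapping through
this architecture — not that the model generalises to photographs.

## Problem sizes and numerical choices

The reference configuration (`small_config()`) has roughly $10^5$
parameters: an 8 x 8 grid, EFE with all four kernel sizes at 8 channels per
branch and width 24, a 2-layer encoder of width 24 with 4 heads, a 2-layer
decoder with a 64-wide output, and a 768-unit head. The recovery experiment
trains it on 500 synthetic images for 30 epochs and scores 100 held-out
images; the stability ablation trains matched arms (the no-EFE arm swaps the
backbone for a plain embed/3 x 3-conv/1 x 1 stem whose hidden width is
chosen to match the EFE parameter count within a few percent, with a GELU
after the convolution as a conventional stem would have) on 240 images for
12 epochs and compares 20 shared-foreground pairs drawn across five foods.
A run's stability scalar is the median over nutrient classes of the
per-nutrient median (across pairs) prediction variance. These sizes are the
package's defaults for a single-CPU workflow; everything scales through the
configuration.

Other numerical conventions: bilinear resampling uses centre-aligned
coordinates with edge clamping (so upscaling preserves corner pixels
exactly); rotation fills out-of-frame samples by reflection rather than a
constant, to avoid injecting an artificial background; augmentation happens
after intensity rescaling (the order is otherwise unconstrained); layer
normalisation uses $\epsilon = 10^{-5}$; softmax rows are max-shifted before
exponentiation; weight initialisation is fan-in-scaled uniform, fully
seeded. All randomness — data order, initialisation, dropout, rendering —
derives from integer seeds through a single hash-based stream splitter, so
every run in the package is bit-reproducible.

## Known limitations

* The plane-level MDN routing is non-differentiable; a plane sitting near a
  partition boundary can switch groups between steps, which adds a small
  amount of optimisation noise. The same discreteness makes the routing
  itself background-sensitive: a background change alone can flip a few
  percent of plane assignments, so on the synthetic universe — where both
  ablation arms train to near-total background invariance anyway — the
  stability comparison between the EFE and plain-stem arms sits in the noise
  floor and does not reproduce a directional EFE advantage. Demonstrating
  that advantage appears to need a regime where background clutter actually
  degrades the baseline, which these renders do not create.
* Sleeping is driven by activity statistics shared across the batch, and
  frozen values are stored per token, not per sample; with very small
  batches the statistics are noisy.
* The decoder applies sleeping only during training; if the goal were
  inference speedup, an eval-time pruning rule would be needed, and none is
  defined here.
* The regression top-1/top-5 scores compare content magnitudes, not class
  identities; two classes with similar content values are interchangeable
  under the metric.

## Worked example

```{r, eval = FALSE}
library(nutrinet)

spec <- synthetic_spec()
train <- generate_dataset(spec, 200, seed = 1)
fit <- train_model(train$samples, small_config(seed = 1), epochs = 10, seed = 1)
glance(fit)
autoplot(fit)

test <- generate_dataset(spec, 50, seed = 2)
evaluate_model(test$samples, fit)$summary

sample <- test$samples[[1]]
predict(fit, sample$image)
```
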