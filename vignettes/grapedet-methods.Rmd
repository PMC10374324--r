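---
title: "Methods: attention-augmented single-stage grape-bunch detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-augmented single-stage grape-bunch detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Harvesting robots need to find grape bunches in scenes that are anything but
tidy: bunches overlap, leaves hide most of a cluster, illumination swings
from back-lit glare to deep shade, and fog or rain can wash out contrast.
`grapedet` implements a single-stage, anchor-based detector built for this
setting. Three ideas distinguish it from a plain YOLO v4 detector:

1. **Parameter-free attention (SimAM).** After every feature-extraction
   stage of the CSPDarkNet-53 backbone, each activation $t$ of a channel is
   assigned a minimal energy
   $$e^*_t = \frac{4(\hat\sigma^2 + \lambda)}{(t-\hat\mu)^2 + 2\hat\sigma^2 + 2\lambda},$$
   where $\hat\mu$ and $\hat\sigma^2$ are the mean and *population* variance
   over all $M$ pixels of that channel and $\lambda = 10^{-4}$. The feature
   map is reweighted as $\tilde X = \mathrm{sigmoid}(1/e^*) \odot X$.
   Activations far from their channel mean get energies below 2 and hence
   weights above $\mathrm{sigmoid}(1/2)$; a constant channel has $e^* = 2$
   everywhere. The block has no learnable parameters, so toggling it leaves
   the model's parameter count unchanged — an invariant the test suite
   asserts.

2. **Weighted bidirectional fusion with a jump connection (the improved
   path-aggregation neck).** The top-down path upsamples the deep,
   semantically rich maps and fuses them with the shallower, better-located
   maps; the bottom-up path then rebuilds the coarse scales. Where a plain
   neck concatenates, this neck *adds* inputs under fast-normalized weights
   $w_i = \mathrm{relu}(r_i) / (\sum_j \mathrm{relu}(r_j) + \varepsilon)$,
   $\varepsilon = 10^{-4}$, with one learnable raw scalar $r_i$ per edge,
   initialized to 1. The stride-16 output node takes three inputs: the
   top-down intermediate map, the downsampled fine-scale output, and a jump
   connection straight from the backbone tap,
   $$P_4'''' = \mathrm{Conv}(w_0 P_4'' + w_1\,\mathrm{Down}(P_3'') + w_2 P_4).$$
   The convolution group after each fusion is a standard 3×3 followed by a
   1×1 convolution, and the fusion module is executed once (not repeated).

3. **Focal/CIoU composite loss.** Confidence and class probabilities are
   trained with focal-modulated binary cross-entropy ($\alpha = 0.75$,
   $\gamma = 2$), box regression with the Complete-IoU loss, summed over the
   three prediction scales and divided by the batch size, with balance
   coefficients $\lambda_{conf} = \lambda_{cls} = \lambda_{loc} = 1$.

## Architecture details

The backbone follows the CSP design: each of the five stages downsamples
with a stride-2 3×3 convolution, splits channels into a bypass branch and a
residual-stack branch (1, 2, 8, 8, 4 residual blocks), merges them by
concatenation and a 1×1 convolution, and ends with SimAM. With a 608 px
input and base width 32, the three taps have shapes 76²×256, 38²×512 and
19²×1024. All backbone convolutions use Conv–BatchNorm–Mish; the neck and
heads use Conv–BatchNorm–LeakyReLU (slope 0.1); head output convolutions are
plain 1×1 with bias. The deepest tap passes through an SPP block (parallel
5/9/13 max-pools, stride 1, same padding, concatenated with the identity).
Each head emits $3(5 + C)$ channels per cell: box offsets $(t_x, t_y, t_w,
t_h)$, objectness, and $C$ class logits per anchor.

One stage-labelling ambiguity was resolved in favour of uniformity: SimAM is
attached after **all five** stages (a per-stage logical mask is exposed for
ablations), since the design principle is that every stage output is
refined.

### The network engine

No deep-learning framework is available in this R stack, so the package
ships a compact reverse-mode automatic-differentiation engine over `(H, W,
C)` arrays. Convolution is im2col (C++) plus a BLAS matrix product; pooling,
upsampling, activations, batch norm, SimAM and the fusion node are composed
ops with analytic adjoints, each validated against central differences in
the test suite. Images are processed one at a time with gradient
accumulation across the batch.

**Normalization statistics.** Because the engine normalizes one sample at a
time, batch-norm uses the *current sample's* per-channel statistics both in
training and in inference (instance-style batch normalization). This keeps
training and inference activations identical — important when overfitting
tiny datasets, where running-average statistics computed from batches of one
or two images would systematically disagree with the statistics of any
single image — and inference remains deterministic. Running moments are
still tracked and checkpointed for diagnostics.

## Anchors

Anchor priors come from K-means over the ground-truth (width, height) pairs
with distance $d = 1 - \mathrm{IoU}$ for corner-anchored boxes — the metric
that matches the IoU-style "accuracy" the method reports — with
Euclidean distance available behind a flag. Centers update as per-cluster
means; ties and empty clusters are repaired by reseeding from the point
farthest from its center; ten seeded restarts keep the lowest total
distance. The reported accuracy is the mean over boxes of the best IoU to
any anchor (the natural reading of a percentage quality score for a
clustering of box shapes). A caveat worth stating: with the $1-\mathrm{IoU}$
distance, the mean-update step is a heuristic (the mean minimizes squared
Euclidean distance, not IoU distance), so monotone descent of the total
distance is checked empirically per iteration rather than guaranteed; on all
seeded test populations it holds. Nine anchors are grouped three per scale
by area (ties broken by width), largest on the coarsest grid.

## Training recipe

Two stages: first the backbone is frozen (30 epochs, batch 8, initial
learning rate $10^{-3}$), then everything fine-tunes (10 epochs, batch 2,
$10^{-4}$). Cosine annealing runs within each stage and restarts at the
boundary, decaying to 1% of the initial rate. Class targets are
label-smoothed with $\varepsilon = 0.005$ (positives $1 - \varepsilon/2$,
negatives $\varepsilon/2$); the symmetric form is used because with a single
class the $y(1-\varepsilon) + \varepsilon/K$ form would be inert. Input
content is randomly rescaled inside the letterboxed canvas by a factor drawn
from $U(0.7, 0.9)$. Mosaic 4-image composites are implemented as an optional
batch-time augmentation, off by default. The optimizer is Adam (the recipe
names only the learning rates; Adam is the package's default choice, with
the settings recorded as configuration, not as a claim about the original
experiments). Target assignment is the standard one-best-anchor scheme: each
box trains the best wh-IoU anchor at the cell containing its center;
non-best anchors with wh-IoU above 0.5 are ignored (removed from the
no-object mask).

Numerical choices: natural logarithms throughout; probabilities clamped to
$[10^{-7}, 1-10^{-7}]$; box log-sizes clamped to $\pm 10$ with a
straight-through gradient so saturated units can recover; the CIoU
trade-off coefficient $\alpha_{\mathrm{CIoU}} = \nu/((1-\mathrm{IoU})+\nu)$
is treated as a constant during backpropagation, the standard practice for
this loss.

## Augmentation operators

Five box-aware operators expand a dataset exactly sixfold (originals plus
one variant each): multiplicative brightness (gain drawn from [0.6, 1.4]),
Gaussian blur ($\sigma \in [1, 3]$), random affine (rotation ≤ ±15°, scale
0.8–1.2, translation ≤ 10%; boxes are mapped through the same transform as
the axis-aligned hull of their corners and dropped below 25% visible area),
horizontal mirror, and raindrop streaks (about 200 translucent near-vertical
streaks at full intensity). A fog transform blends each pixel toward an
airlight of 240 with transmission $1 - \text{intensity} \cdot g(x,y)$, $g$ a
smooth seeded spatial field. The published figures show these effects only
qualitatively, so the parameter ranges above are package defaults, all
configuration-exposed. Raindrop is an overlay model, not a lens-refraction
simulation — it reproduces the visual character of the augmentation at a
fraction of the complexity.

## Synthetic scenes and what the tests can (and cannot) show

The generator renders orchard-like scenes: a low-frequency mottled green
background, bunches as clusters of 18–35 shaded berry ellipses under a stem,
leaf-shaped occluders grown until they cover a requested fraction (up to
0.8) of the bunch mask within ±2%, and front/back/low illumination grades.
Ground-truth boxes always cover the full bunch extent, occluded or not —
matching how whole clusters are annotated in vineyard datasets. Rendering is
a pure function of the scene specification.

These scenes exercise geometry, occlusion bookkeeping and the full
train/detect loop, but they are not photorealistic: berries lack specular
texture, backgrounds lack true foliage structure, and class appearance is
uniform. Passing the overfit smoke test therefore demonstrates that the
architecture, loss, decoding and evaluation stack are wired correctly and
can fit data — it says nothing about detection accuracy on real vineyard
imagery, which requires GPU-scale training on a real dataset and is
deliberately out of scope.

## Problem sizes used by the tests and the acceptance script

Desk-scale problem sizes were chosen so the whole suite runs comfortably on
a single CPU: the smoke test trains a reduced model (96 px input, base width
8, one residual block per stage, ~1.4 M parameters) for 200 steps on two
96 px scenes with two bunches each, with anchors clustered from a 36-box
synthetic population; the architecture-shape checks build the full-size
608 px model (61 M parameters) and run one forward pass. The expansion
factor is measured on twenty 64 px scenes. The smoke test's random-scale
augmentation is disabled (its two-image overfit target makes geometric
jitter counterproductive), while the training-pipeline tests cover the
0.7–0.9 rescaling separately.

## Known limitations

- Training throughput is modest (single CPU, double precision); the package
  is a reference implementation and desk-scale experimental tool, not a
  production trainer.
- Per-sample normalization statistics mean very small feature maps (1×1)
  carry no normalization signal; the smallest supported input is 32 px.
- The VOC reader accepts 0- and 1-based coordinate dialects verbatim; a
  1-pixel convention difference is below the tolerance of every IoU-level
  check but matters if exact corner equality with another tool is required.
- JPEG reading is supported via the imaging backend, but all package
  outputs are PNG.
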