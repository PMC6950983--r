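---
title: "Methods: dense-encoder U-Net segmentation of cell nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense-encoder U-Net segmentation of cell nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions it fixes,
and the design choices made where the design was genuinely open.

## The segmentation problem

Grey-scale bright- or dark-field microscopy images contain tens to hundreds
of cell nuclei of varying size, intensity and density, on an unevenly
illuminated background. The task is semantic segmentation (nucleus versus
background) followed by instance extraction: every connected predicted
region is one cell. The emphasis is on *light-weight* models — few enough
weights that training and inference remain feasible without a GPU — which
is why the package provides three architectures of the same family built
from identical block conventions, differing only in topology, so that any
accuracy difference is attributable to structure alone.

## Architectures

All convolutions are 3x3, stride (1,1), zero-padded ("same"), followed by
ReLU; down-sampling blocks are the same conv with stride (2,2); the head is
a single 1x1 convolution with sigmoid activation. Filters at level
$n = 1, \dots, N$ are $2^{\,n-1} B$ with depth $N = 5$ throughout and the
base width $B$ a multiple of 2.

**Reference U-Net** (`arch = "unet"`): two conv blocks per level, 2x2
max-pooling, decoder by 2x2 transposed convolution halving the channel
count, skip concatenation, two conv blocks. Following its widely used
reference implementation, the blocks carry **no batch normalisation**; with
plain biases the weight totals are 1,940,817 (B = 16) and 485,673 (B = 8),
i.e. the familiar 1.941 / 0.486 M figures.

**Nested U-Net** (`arch = "unet_pp"`): the same backbone plus the dense
grid of re-sampling nodes $X_{i,j}$, where node $(i,j)$ concatenates all
previous outputs of level $i$ with the 2x2 transposed-conv up-sampling of
$X_{i+1,j-1}$ and applies two conv blocks. No deep supervision and no
pruning — the head reads $X_{1,4}$ only. Totals: 2,261,601 / 566,001
(2.262 / 0.566 M). An L2 penalty on conv kernels defaults to
$\lambda = 10^{-4}$ at B = 16 and 0 at B = 8.

**Dense-encoder U-Net+** (`arch = "unet_plus"`): the encoder is redesigned
as chains of conv blocks per level, chain lengths **(5, 4, 2, 1)** from the
full-resolution level down. The first block of each deeper level consumes a
down-sampling block from above; every later chain block concatenates
exactly two tensors — its predecessor at the same level and another
down-sampled column from the level above — so kernel widths stay at $2c$
rather than growing along the skip pathway as in the nested variant. The
final down block of each level is shared between the next level's chain
and a *direct pathway* that carries that level's encoded features,
unconvolved, one and two levels further down, into the decoder
concatenations. The deepest level is reached by a single down block (16B
filters) with no further convs. Each decoder stage concatenates the deeper
up-block output, the same-level chain output and the direct tensors, then
up-samples — either a 3x3 stride-2 transposed convolution (output channels
$2^{\,n-1}B$, i.e. half its input schedule) or parameter-free repetition
up-sampling — followed by two conv blocks. Conv and down blocks carry
batch normalisation (counted at the framework convention of four
parameters per channel: scale, shift, moving mean, moving variance, plus
the conv bias); transposed convolutions and the head carry a bias only.

Where the published figure of this family leaves the encoder wiring
ambiguous, the package pins it by a hard constraint: the wiring above
reproduces **all eight** published weight totals simultaneously —
1,926,209 / 483,873 for the transposed-conv variant and 1,730,129 /
434,793 for the up-sampling variant at B = 16 / 8 (1.926, 0.484, 1.730,
0.435 M) — and the difference between the two up-sampling modes is exactly
$765B^2 + 15B$, which also fixes the conventions "3x3 transposed conv,
bias but no batch norm on the up-sampling op, channel halving before the
two decoder convs". The same totals are only reachable with batch-norm
parameters included for U-Net+ and excluded for the two reference
builders, which is how the `batch_norm` default is chosen per
architecture. `summarize_architecture()` prints the complete per-block
accounting; its column sum equals `count_weights()` by construction.

The dense-encoder wiring is defined for depth 5 (the published setting);
other depths are rejected rather than extrapolated.

## Preprocessing

`preprocess()` composes, in fixed order: CLAHE (contrast-limited adaptive
histogram equalisation; default 8x8 tile grid and normalised clip limit
0.01, delegated to EBImage), Chambolle total-variation denoising (default
weight 0.1, implemented as the standard dual projection iteration with
stopping tolerance 2e-4 and at most 200 iterations; weight 0 returns the
input exactly), and rescaling of the observed range to [0, 1] (a constant
image maps to zeros — the degenerate-case convention). The same pipeline
serves training and inference. The CLAHE/TV parameter values are not
reported for the original experiments, so they are package defaults,
exposed in `preproc_config()`.

## Patch pipeline

Training operates on 256x256 patches. `grid_patches()` crops every patch
whose top-left corner lies on the structured grid with spacing
$\Delta x = \Delta y = 256$; dimensions below 256 are zero-padded,
dimensions above but indivisible by 256 get boundary re-crops whose far
edge coincides with the image edge, so the union of footprints covers every
pixel. `random_patches()` adds uniformly positioned patches kept only when
foreground/background pixel count ratio **strictly** exceeds 0.4 (the
literal reading of the published rule); rejection sampling is bounded, so
fewer patches may be returned. `split_train_val()` partitions at patch
level 8:2 (`round(0.8 n)` training patches), deterministically under the
configured seed; patch-level splitting follows the published protocol even
though it can leak nearby content between the sets — an image-level split
can be had by splitting samples before patch extraction.

Augmentation draws from Gaussian/median/average blur, contrast, hue and
saturation adjustments (image only) plus flips and right-angle rotations
(applied identically to the mask). Hue/saturation on a grey-scale image is
reconciled by stacking to three equal channels, perturbing in HSV space and
converting back through luminance — for truly grey inputs this is nearly a
no-op, which simply reflects that those augmentations were designed for the
colour images the package deliberately filters out. In the pipeline driver
augmentation precedes preprocessing and patch extraction, matching the
published order; the number of random patches per image (default 4) and of
augmented copies are unreported in the original protocol and are config
knobs.

## Training

The objective is
$\mathcal{L} = \lambda_{\mathrm{BCE}}\,\mathcal{L}_{\mathrm{BCE}} +
\frac{1}{M}\sum_{i=1}^{M} -\log D(y^i_{\mathrm{true}}, y^i_{\mathrm{pred}})$
with $\lambda_{\mathrm{BCE}} = 1$ and the soft Dice coefficient
$D = (2\sum y_t y_p + s)/(\sum y_t + \sum y_p + s)$. The smoothing constant
$s$ (default 1e-6, added to numerator and denominator) keeps $-\log D$
finite on empty intersections; probabilities are clipped to
[1e-7, 1 - 1e-7] inside the cross-entropy. The per-sample index of the sum
runs over the $M$ samples of the batch — the only reading under which the
two terms are commensurate. Optimisation is Adam at learning rate 5e-4 for
20 epochs by default; the validation loss is evaluated every epoch and the
parameters at its minimum are returned (best-checkpoint rule). Optional
fine-tuning continues for 5 epochs at 1e-4 (the first of the two published
options) with a fresh optimiser state; the incoming model counts as the
initial checkpoint, so fine-tuning can never worsen the best monitored
loss. Batch size defaults to 16 and is a free parameter ("fill the
hardware" is not a portable rule).

The engine itself — im2col/col2im convolutions, transposed convolutions,
batch normalisation, max-pooling, Adam — is part of the package
(RcppArmadillo kernels orchestrated over an explicit block graph).
Convolution arithmetic runs in single precision, the customary CNN
training precision; batch-norm statistics use $\varepsilon = 10^{-3}$ and
moving-average momentum 0.9 (config-exposed; a shorter memory than the
usual 0.99 suits the short CPU-scale trainings the package targets).
Gradient correctness was established against central finite differences in
a double-precision build of the same kernels. Exact padding follows the
TensorFlow "same" convention (excess padding at bottom/right), which is
what makes the stride-2 blocks and their adjoints shape-consistent at
every level.

## Inference

`predict_image()` preprocesses, decomposes into patches by the same grid
rules, forward-passes every patch (batch-norm in moving-statistics mode)
and fuses overlaps by the pixel-wise **maximum** over covering patches;
padding is cropped so output shape equals input shape. On exact tilings
fusion degenerates to stitching. `binarize_and_clean()` thresholds at
probability strictly greater than 0.5, removes 8-connected foreground
components below `min_object_area` and fills 4-connected enclosed holes
below `max_hole_area` (the standard foreground/background connectivity
duality; both areas default to 300 px, a mid-range reading of "several
hundred pixels"); the operation is idempotent. `label_instances()` labels
8-connected components 1..K.

## Evaluation

`iou_matrix()` computes pairwise intersection-over-union between
ground-truth and predicted cells. `match_cells()` assigns predictions to
ground-truth cells one-to-one, greedily on descending IOU with ties broken
by lower predicted label; at each threshold $T_k \in \{0.50, \dots,
0.95\}$ a match requires IOU $> T_k$ strictly. Because any pair with IOU
above 0.5 is mutually exclusive (two predictions cannot each overlap the
same cell by more than half the union), the greedy assignment attains the
maximum matching at every threshold in this range — the test suite verifies
equality against an exhaustive-assignment oracle on randomly perturbed mask
pairs. Unmatched ground-truth cells are false negatives, unmatched
predictions false positives. Each ground-truth cell is also assigned one
value for the average-IOU statistic: its matched IOU when above the
assignment threshold (default 0.50, the most inclusive member of the
threshold collection), else 0.0. Dataset aggregation reports the mean and
*population* standard deviation of per-image average IOUs and the mean
per-image precision; an image with neither ground-truth nor predicted
cells counts as vacuously perfect (avoids 0/0), and one with ground truth
but no predictions scores 0.

## The synthetic generator

`generate_sample()` emulates the features of grey-scale nuclei images that
drive the pipeline: elliptical nuclei (semi-axes 8–12 px by default,
10–15 per 256x256 field) with per-nucleus intensity (0.55–0.95) on a
background at 0.15 with a linear illumination gradient of amplitude 0.10
in a random direction, Gaussian blur ($\sigma = 1$) softening the nucleus
boundaries — the boundary-ambiguity failure mode that dominates real
segmentation errors — and additive Gaussian noise ($\sigma = 0.02$),
quantised to 8-bit so that written PNGs round-trip exactly. Placement is
rejection sampling; with touching disallowed, instances keep at least one
background pixel between them (also diagonally), and a bounded retry
budget turns impossible densities into an explicit placement error. One
RNG stream per (seed, index) pair makes every sample independently
reproducible. The generator does **not** emulate colour stains,
fluorescence channels, overlapping/touching nuclei clusters, texture
inside nuclei, or annotation error; passing tests on synthetic data
therefore demonstrate that the machinery is correct and trainable, not
that published accuracy on real microscopy data is matched — reproducing
those values would require the external contest dataset and GPU-scale
training.

## Problem sizes used by the tests

The end-to-end checks train the B = 8 dense-encoder network on 8 generated
256x256 patches for 30 epochs at batch size 1 and learning rate 5e-3 — an
overfit-capacity setting chosen so a CPU run finishes in minutes — and
then require training soft-Dice at least 0.90 and mean per-cell IOU at
least 0.5 after inference and cleanup on the same images. The
post-processing there uses `min_object_area = 100` because synthetic
nuclei occupy roughly 200–450 px, so the dataset-oriented default of 300
would delete the smallest legitimate nuclei. Unit tests use B = 2 models
on 64x64 inputs.

## Known limitations

Touching nuclei merge into one predicted instance (no watershed or other
instance-splitting — the pipeline relies on the generator/dataset having
separated cells); the dense-encoder wiring is fixed to depth 5; training
is single-device CPU with no learning-rate schedules beyond the two-phase
protocol; hue/saturation augmentation is essentially inert on grey-scale
input by construction; and the stage-2 contest layout, colour
preprocessing and dataset downloads are out of scope.
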