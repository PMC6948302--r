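---
title: "Multiscale dilated-convolution U-net segmentation: model and methods"
author: "msunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale dilated-convolution U-net segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msunet)
```

# The problem

Hippocampus segmentation in brain MRI — and low-contrast biomedical
segmentation generally — is hard for classical methods because the target
occupies a small fraction of the image, its mean intensity differs from the
surrounding tissue by only a fraction of the noise amplitude, its boundaries
are blurred by partial-volume effects, and a smooth bias field modulates
intensities across the field of view. `msunet` implements an end-to-end
encoder–decoder convolutional network for this regime, together with the
preprocessing, augmentation, loss, metrics and training protocol that make
it reproducible, and a synthetic phantom generator so the entire pipeline
can be exercised and validated without any external data.

# The network

The model has three parts.

**Multiscale stem.** Five parallel convolution branches read the 1-channel
slice: a 1×1 branch, a factorized 3×3 (1×3 then 3×1), a factorized 5×5
(1×5 then 5×1), a 3×3 with dilation 2, and a 3×3 with dilation 4 — each 16
channels wide by default, each followed by batch normalization and ReLU,
each zero-padded to preserve the spatial size so the five outputs
concatenate to 80 channels. Two trailing 3×3 convolutions map the
concatenation to 32 channels, and a 2×2 max-pool closes the stem.

Dilation widens the receptive field without adding parameters. For a
stride-1 stack the field grows by $(F-1)\,d$ per layer from $RF_0 = 1$:

```{r rf}
plans <- list(conv_plan(3, dilation = 1),
              conv_plan(3, dilation = 2),
              conv_plan(3, dilation = 4))
vapply(1:3, function(k) stacked_receptive_field(plans[1:k]), 0L)
```

A single 3×3 sees 3 pixels; stacking the dilation-2 and dilation-4 layers
grows the field to 7 and then 15. `measure_receptive_field()` verifies the
recurrence empirically by backpropagating an impulse through an
instantiated stack with strictly positive weights and measuring the support
of the input gradient; the test suite requires formula and measurement to
agree for every convolution geometry the default network uses. Two readings
of the dilated branches exist: as parallel single layers (receptive fields
3/5/9) or as the cumulative 1→2→4 stack (3/7/15). The default network wires
them in parallel, which is the cheaper layout; the receptive-field auditor
reports the stacked progression, which is the multiscale design rationale.

**U-net body.** Every in-block convolution is a zero-padded, stride-1 3×3,
so by the output-size relation
$I_\text{out} = \lfloor (I_\text{in} - F + 2P)/S \rfloor + 1$ (floor
division; $F{=}3, P{=}1, S{=}1$) it preserves the spatial size. Downsampling
is done by explicit 2×2 stride-2 convolutions rather than pooling. Each
contracting block has two 3×3 convolutions (BN + ReLU after each); its
first convolution doubles the channel count. With the default input of
128×128 and four halvings, resolution contracts 128 → 64 → 32 → 16 → 8
while channels grow 64 → 128 → 256 → 512 → 1024 at the 8×8 bottleneck.
The expanding path has three deconvolution blocks: a 3×3 stride-2
transposed convolution doubles the resolution and halves the channels, the
result is cascaded (channel-concatenated) with the matching-resolution
contracting block's features, and two 3×3 convolutions halve the combined
width again.

**Decoder head and classifier.** The fourth and final upsample lives in a
decoder head of one transposed convolution plus one convolution (BN + ReLU
each), restoring the input resolution; a 1×1 convolution reduces to one
feature map, and a sigmoid yields the per-pixel foreground probability. A
2-channel softmax classifier is available as a configuration option
(`classifier = "softmax_2ch"`); it is mathematically a sigmoid of the logit
difference, and the single-channel sigmoid is the default because the task
is binary and pairs naturally with the Dice loss. Probabilities are
thresholded at 0.5 by default, with the *greater-or-equal* convention at
the boundary.

```{r audit}
audit_network(network_config())
```

The static audit above is computed purely from the size formula;
`build_network()` instantiates the same plan with glorot-normal weights
(variance $2/(\text{fan}_{in}+\text{fan}_{out})$, seeded), and the test
suite checks that instantiated shapes match the audit at every exposed
stage. `count_parameters()` reports trainable counts (weights + biases +
2 per BN channel) for any plan, layer or block, and is required to agree
with the engine's allocated arrays; note that the stem's post-concatenation
3×3 convolutions alone contribute tens of thousands of parameters, so even
narrow configurations sit far above a few thousand parameters in total.

Two reconciliations were needed to make the printed channel plan
self-consistent. First, a uniform 16-channel stem cannot feed a first U-net
block that doubles to 64, so the stem's trailing width defaults to
`base_width / 2` (32): the first block's doubling then lands exactly on 64.
Second, a stride-2 stem pool would contract 128×128 to a 4×4 bottleneck
after the U-net's four halvings; the default therefore keeps the stem pool
at stride 1 (size-preserving, padded on the far edges), leaving all four
halvings inside the U-net, with `stem_pool_stride = 2` exposed for
experiments with the alternative reading.

# Loss and metrics

Training minimizes the region-based soft Dice loss over the $v$ pixels of
one image block,

$$\mathcal{L}(g, p) = 1 - \frac{2\sum_i^v p_i g_i + \varepsilon}
{\sum_i^v (p_i^2 + g_i^2) + \varepsilon},$$

with probabilities $p$ and binary labels $g$. Background pixels contribute
nothing to the numerator and no $g^2$ term, so the loss is governed by the
foreground region rather than the (dominant) background — the property
that makes it suitable for heavily imbalanced segmentation. The smoothing
constant $\varepsilon = 10^{-7}$ makes the empty-vs-empty case well defined
(loss 0); an alternative reading that also masks the $p^2$ term to
ground-truth foreground is available via `masked_background = TRUE` but is
not the default, since the plain form is the one whose hard-prediction
value equals $1 - \mathrm{DSC}$ exactly. Batch losses are means of
per-sample losses. The analytic gradient used for backpropagation is
finite-difference-checked in the test suite.

Evaluation uses the standard overlap family, from confusion counts TP, FP,
FN: $\mathrm{DSC} = 2TP/(2TP+FP+FN)$, $\mathrm{SEN} = TP/(TP+FN)$,
$\mathrm{PPV} = TP/(TP+FP)$, $\mathrm{IoU} = TP/(TP+FP+FN)$. The identities
$\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ and
DSC = harmonic mean(SEN, PPV) are enforced as property tests over 1000
random mask pairs. Degenerate denominators follow a bounded convention: a
metric whose reference set is empty scores 1 if the compared set is also
empty and 0 otherwise. Aggregation over a test set is per-case mean (not
pixel-pooled), which weights every case equally regardless of lesion size.

# Preprocessing

`extract_roi()` crops image and mask with identical half-open bounds
(0-based voxel semantics, row-major, centre clamped minimally so the window
stays inside the volume); it never changes pixel values. The default 2D
patch is 128×128 (a 256×256 slice crops to its central 128×128); the 3D
convention is 80×80×40 around the structure's centroid.
`normalize_gray()` standardizes to mean 0 and *population* SD 1 (divide by
$N$; made explicit because "the SD" is ambiguous), per image rather than
per dataset — per-image statistics keep inference self-contained, and
dataset-global statistics can be passed via the `stats` argument. The
composition order is crop-then-normalize, so statistics are computed on the
ROI the network actually sees. Normalization is idempotent to within
$10^{-6}$ and refuses constant images.

# Augmentation

Five paired transforms: vertical flip, horizontal flip, random rotation
(default ±15°), random translation (default up to 10% of the extent, whole
pixels) and elastic deformation (Gaussian-smoothed random displacement
field, $\alpha = 10$ px magnitude, $\sigma = 4$ px smoothness — the
standard biomedical recipe). Geometric parameters are sampled once per call
from the spec's seed and applied identically to image and mask; images are
resampled bilinearly, masks by nearest-neighbour so they remain strictly
binary; out-of-frame regions fill with 0 (background). Separately,
`expand_dataset()` performs offline rotation expansion: each pair yields
{identity, +90°, −90°, 180°}, quadrupling the collection (100 pairs → 400)
with exact pixel permutations. Two derived rotations alone cannot quadruple
a collection, so this four-variant scheme is the minimal rotation-only plan
consistent with a 4× expansion. Each variant records its source index, and
`split_dataset()` groups by that provenance so augmented copies never
straddle the train/test boundary. Online augmentation during training
(re-seeded per epoch and sample) and offline expansion can be combined.

# Training protocol

Defaults: learning rate 0.001, batch size 8 (gradient accumulation over
single-image forward/backward passes, averaged), L2 regularization $10^{-4}$,
glorot-normal initialization, 80/20 train/test split. The optimizer is Adam
with *decoupled* L2 (applied directly to convolution weight matrices, not
through the moment estimates; BN parameters and biases are not decayed);
plain SGD is available. Epochs default to 50 with best-epoch (lowest mean
training loss) checkpoint retention. Batch-norm statistics are computed per
sample over spatial positions during training — the natural scheme when
images pass through one at a time — with running means/variances
(momentum 0.99, $\varepsilon = 10^{-5}$) used in evaluation mode, which
makes inference deterministic. Everything downstream of the seed is
reproducible bit for bit: initialization, epoch shuffles (epoch-derived
seeds), augmentation draws, and therefore loss histories, weights and
predictions.

# The phantom generator

`generate_phantom()` emulates the statistical regime of low-contrast
anatomy: a small number of randomly placed, sized and oriented ellipses
(ellipsoids in 3D) rasterized as the binary mask; the blob profile blurred
by a Gaussian of width `blur_sigma` (default 1.5 px) to soften boundaries;
a smooth low-order cosine bias field (peak-to-peak `bias_amplitude`,
default 0.2) mimicking MRI inhomogeneity; and additive Gaussian pixel
noise. The clean image is calibrated so the mask-foreground mean exceeds
the background mean by exactly `contrast`, which makes the
contrast-monotonicity property exact and testable. The default regime —
contrast 0.3, noise SD 0.2, three blobs on a 64² grid, foreground fraction
in the 1–30% range — is deliberately below the single-pixel separability
threshold: thresholding the noisy image cannot recover the mask, so a
model that reaches high DSC must be exploiting spatial context.

What the phantoms do *not* emulate: anatomy (shapes are convex ellipses),
MRI physics (Rician noise, k-space artefacts, partial-volume mixtures),
inter-subject variability, or annotation noise. Passing the phantom
benchmarks therefore demonstrates that the architecture, loss, gradients
and training loop are correct and that the network can learn
low-contrast segmentation from context — not that any particular clinical
accuracy would be attained on real scans.

# Validation protocol and problem sizes

The automated suite validates learning at three scales, chosen to exercise
the full machinery while remaining desk-sized:

* **Single-pair overfit** — one noise-free high-contrast 32² phantom,
  reduced network (base width 8, three halvings), learning rate 0.01,
  ≤ 200 steps, required to drive the Dice loss below 0.1. Single-sample
  optimization tolerates (and benefits from) a step size an order above
  the full-data default.
* **Noise-free generalization** — 20 high-contrast 64² phantoms, 16/4
  split, base width 16, four halvings, learning rate 0.003, 40 epochs;
  required mean test DSC ≥ 0.95.
* **Low-contrast generalization** — 20 phantoms at the standard
  contrast-0.3 / noise-0.2 regime, same network, 25 epochs; required mean
  test DSC ≥ 0.80.

The reduced widths preserve every structural element of the default
network (stem branches, doubling plan, skip cascades, decoder head) while
keeping each run in the minutes range on one CPU core.

# Numerical choices and degenerate inputs

* Output sizes use floor division; a nonpositive size is a geometry error.
* Transposed convolutions resolve the stride-2 output-size ambiguity by
  explicit targeting (output = 2 × input), implemented as the exact adjoint
  of the corresponding stride-2 convolution.
* Thresholding uses ≥, so ties go to foreground.
* Dice loss: $\varepsilon = 10^{-7}$; loss of an empty prediction against
  an empty truth is 0.
* Metrics on empty sets use the bounded 1/0 convention described above.
* `normalize_gray()` rejects images with fewer than 2 pixels or zero SD;
  crops that cannot contain the mask foreground raise a coverage error
  rather than silently truncating the label.
* Phantom amplitude calibration divides by the foreground/background gap
  of the blurred blob profile, which is strictly positive by construction.

# Known limitations

* 2D slices are the primary operating mode; volumes are handled slice-wise
  (the generator and preprocessing are fully 3D, the network is 2D).
* Per-sample BN is not identical to cross-image batch statistics; with
  batch accumulation the two differ, though running statistics converge to
  similar values in practice.
* The compute engine is single-threaded CPU (im2col + GEMM); it is sized
  for the validation protocol above, not for full-resolution clinical
  training runs.
* The phantom generator's additive Gaussian noise model is documented as
  swappable but is the only model implemented.
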