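# msunet

Multiscale dilated-convolution U-net for low-contrast biomedical image
segmentation, in pure R (with an RcppArmadillo compute engine).

Segmenting small, low-contrast structures — the hippocampus in brain MRI
being the canonical case — defeats intensity-based methods: the target's
mean gray level sits well inside the noise band of the surrounding tissue,
boundaries are blurred, and a smooth bias field drifts across the image.
`msunet` implements an end-to-end encoder–decoder network for this regime
and everything needed to train and validate it reproducibly, including a
seeded synthetic phantom generator so the whole pipeline runs with no
external data.

## The model

* **Multiscale stem** — five parallel branches over the input slice
  (1×1; factorized 3×3 as 1×3·3×1; factorized 5×5; dilated 3×3, d = 2;
  dilated 3×3, d = 4), 16 channels each with BN + ReLU, concatenated and
  fused by two 3×3 convolutions. Stacking the dilation rates 1 → 2 → 4
  grows the receptive field 3 → 7 → 15 pixels at constant parameter cost
  (for stride-1 stacks, RF_l = RF_{l−1} + (F − 1)·d_l).
* **U-net body** — zero-padded 3×3 stride-1 convolutions everywhere
  (⌊(I − F + 2P)/S⌋ + 1 preserves size at F=3, P=1, S=1); 2×2 stride-2
  down-convolutions halve the resolution four times (128 → 8) while
  channels double per block (64 → 1024 at the 8×8 bottleneck); three
  deconvolution blocks (stride-2 transposed 3×3, skip cascade with the
  matching contracting features, two 3×3 convs) climb back up.
* **Decoder head** — a final transposed-conv + conv pair restores the
  input resolution; a 1×1 convolution and sigmoid emit the per-pixel
  foreground probability map, thresholded at 0.5.
* **Loss** — region-based soft Dice,
  `1 − (2Σpg + ε) / (Σ(p² + g²) + ε)`, whose hard-prediction value is
  exactly `1 − DSC`.
* **Metrics** — DSC, SEN, PPV, IoU from confusion counts, with the
  identities DSC = 2·IoU/(1+IoU) and DSC = harmonic mean(SEN, PPV)
  enforced by property tests.
* **Training** — Adam with decoupled L2 (defaults: lr 0.001, batch 8,
  L2 1e−4), glorot-normal init, 80/20 provenance-aware split, full seeded
  determinism.

The convolution/transposed-convolution/batch-norm forward and backward
kernels are implemented in the package (im2col + GEMM in C++); gradients
are finite-difference-verified in the test suite.

## Worked example

Train on 20 synthetic low-contrast phantoms (contrast 0.3, noise SD 0.2 —
below the single-pixel separability threshold, so thresholding cannot
solve it) and evaluate on the held-out 20%:

```r
library(msunet)
spec <- phantom_spec(grid_size = 64, n_blobs = 3, contrast = 0.3,
                     noise_sd = 0.2, seed = 1)
ds <- generate_dataset(spec, 20)
pairs <- lapply(ds, function(p) list(image = normalize_gray(p$image),
                                     mask = p$mask))

cfg <- train_config(learning_rate = 0.003, batch_size = 4, epochs = 25,
                    seed = 1)
sp <- split_dataset(pairs, cfg)                    # 16 train / 4 test

net <- network_config(input_size = 64, base_width = 16,
                      n_down_stages = 4, stem_branch_width = 8)
model <- build_network(net, seed = 1)
fit <- train(model, sp$train, cfg)
tail(fit$history, 3)
#>    epoch       loss
#> 23    23 0.04850498
#> 24    24 0.04489783
#> 25    25 0.04113219

preds <- lapply(sp$test, function(p)
  predict_mask(predict_prob(fit$model, p$image)))
truths <- lapply(sp$test, `[[`, "mask")
evaluate_pairs(preds, truths)
#>   case       dsc       sen       ppv       iou
#> 1    1 0.8487085 0.8712121 0.8273381 0.7371795
#> 2    2 0.8826816 0.9367589 0.8345070 0.7900000
#> 3    3 0.8798883 0.8513514 0.9104046 0.7855362
#> 4    4 0.8800000 0.9205021 0.8429119 0.7857143
#> 5 mean 0.8728196 0.8949561 0.8537904 0.7746075
```

The training Dice loss falls to ~0.04 and the model recovers the blobs on
unseen phantoms at mean DSC 0.87 — far above what any intensity threshold
can reach at this contrast-to-noise ratio. `audit_network(network_config())`
prints the default architecture's full shape/channel table
(128 → 8 spatial, 64 → 1024 channels and back).

A command-line driver covering the whole pipeline
(`generate | preprocess | train | predict | evaluate | audit`) is installed
at `inst/cli/msunet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/msunet.R", package="msunet"))')" \
  audit --set network.input_size=128
```

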