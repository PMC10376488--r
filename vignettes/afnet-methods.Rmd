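---
title: "AFNet: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AFNet: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amniotic fluid volume (AFV) is a diagnostic biomarker for gestational
disorders such as oligo- and polyhydramnios.  On T2-weighted fetal MRI the
fluid appears bright, and the volume can in principle be read off a
slice-wise binary segmentation: AFV = (number of fluid voxels) x (voxel
volume).  The hard part is the segmentation itself — other fluid-filled
structures (bladder, CSF, eyes, oesophagus) share the fluid's intensity
range, fluid pockets have thin crevices, and boundaries are intensity
gradients rather than steps.  A plain intensity threshold therefore cannot
work; the segmentation network has to use shape and context.

This package implements AFNet, an encoder–decoder convolutional network in
the ResUNet++ family, with everything needed to train and evaluate it at
desk scale: a synthetic phantom generator standing in for (legally
unshareable) clinical MRI, the dice-loss training protocol, a metric suite,
volume quantification and a seeded multi-run comparison harness.

## Architecture

All three variants share a common skeleton operating on `(N, H, W, 1)`
grayscale batches with `H`, `W` divisible by 8:

* **Encoder** — a *stem* block at full resolution (two 3×3 convolutions,
  batch norm, ReLU, a projected residual shortcut and a
  squeeze-and-excitation (SE) recalibration), followed by three residual
  blocks whose first convolution and shortcut have stride 2.  Together they
  reduce the spatial dimensions by a factor of 8.
* **Bridge** — atrous spatial pyramid pooling (ASPP): parallel dilated
  convolutions whose rates (6, 12, 18) sample context at multiple scales
  without further downsampling.
* **Decoder** — three stages of (attention gate → upsampling → concatenation
  with the encoder skip → residual block), then a final ASPP, a 1×1
  convolution and a sigmoid, producing a probability map at input
  resolution.

Residual blocks use the pre-activation ordering (BN → ReLU → conv): the
activation is applied *before* the convolution, which matches the
ResUNet-family convention and makes an identity kernel with a linear
activation an exact identity (see `conv_unit()`).

The attention gate combines an encoder skip map `E` at `(2H, 2W)` with the
decoder map `D` at `(H, W)`: each input passes a BN → ReLU → 3×3 conv; the
encoder path is brought to `(H, W)` either by 2×2 max pooling
(`maxpool_original`) or by a stride-2 atrous 3×3 convolution with dilation 2
followed by BN (`atrous_modified`); the sum passes a further BN → ReLU → 3×3
conv and a sigmoid, and the resulting gate multiplies `D` elementwise.  The
pairing of encoder and decoder stages follows `d = -e + B` with `B = 3`
(`attention_index()`).  The sigmoid bounds the gate in `[0, 1]`, so the
gated output never exceeds `|D|` elementwise — a property the test suite
asserts.  The stride-2 atrous convolution uses dilation 2 as the smallest
non-trivial atrous rate; its kernel is 3×3 like every other spatial
convolution in the network.

The three variants differ only in two switches:

| variant     | attention         | upsampling              | parameters |
|-------------|-------------------|-------------------------|-----------:|
| `resunetpp` | `maxpool_original`| nearest neighbour (×2)  | 4.07 M |
| `afnet_noT` | `atrous_modified` | nearest neighbour (×2)  | 4.85 M |
| `afnet`     | `atrous_modified` | 2×2 transposed conv     | 4.80 M |

## Parameter-budget calibration

The encoder filter widths default to `[16, 32, 64, 128]` with a bridge
width of 256.  These defaults were chosen so that `count_parameters()`
reproduces the reference budgets above exactly (4,070,065 / 4,846,449 /
4,802,769 parameters).  Three bookkeeping conventions matter and are fixed
by that calibration:

* **ASPP style.**  Two pyramid styles are implemented.  The `"sum"` style —
  four parallel 3×3 convolutions at rates 1/6/12/18, each with BN, summed
  and fused by a 1×1 convolution — is the style the budgets calibrate
  against and the default in `model_variant()`.  The `"concat"` style —
  five paths (1×1 conv, three atrous convs, a global-average-pooling path
  restored by broadcasting), concatenated and fused — is the richer
  DeepLab-like formulation and is available as a config switch; it adds
  about 0.03 M parameters to the baseline and is not used by the calibrated
  variants.
* **Batch-norm accounting.**  `count_parameters()` counts all state tensors,
  including the batch-norm moving mean and variance (four scalars per
  channel), which is how common framework model summaries report totals.
  `trainable_only = TRUE` excludes the moving statistics.
* **The transposed convolution reduces channels.**  The 2×2, stride-2
  transposed convolution in `afnet` maps the decoder's channel count down to
  the stage width *before* the skip concatenation.  The parameter-free
  upsampling in the other two variants keeps the wider channel count, which
  inflates the first convolution and the shortcut of the following residual
  block.  That saving outweighs the transposed kernel's own weights — which
  is why the full AFNet has slightly *fewer* parameters than AFNet-noT
  despite its learnable upsampling.

## The phantom generator

`generate_slice()` emulates the statistical structure of an
intensity-normalized fluid-bright MRI slice, not its physics:

* fluid regions are randomly rotated ellipses whose boundary radius is
  modulated by low-order angular harmonics (`r(θ) = 1 + Σ a_k sin(kθ +
  φ_k)`, k = 2…5, `a_k ~ N(0, 0.03²)`), producing lobes and crevices;
* confounders are smaller blobs of the same family drawn at the fluid
  intensity ±0.05, placed outside the fluid (with rejection sampling), and
  labelled background — so any global threshold that captures the fluid
  also captures them, which is what forces shape/context learning;
* an optional left-to-right linear gradient and additive Gaussian noise
  soften boundaries; images are clipped to `[0, 1]`.

Intensity defaults (`fluid_intensity = 0.85`, `background_intensity = 0.2`,
`noise_sigma = 0.03`, `gradient_strength = 0.15`) are free parameters of the
phantom, chosen to look like a normalized fluid-bright slice; they are not
calibrated against any real acquisition.  `generate_volume()` extends blobs
into 3-D: each blob has a slice-axis centre, a spherical-cap size profile
and a linear in-plane drift, so adjacent masks overlap as in anatomy.
Clinical sequences carry 50–120 slices per patient and 45 patients is a
typical cohort; the generator defaults mirror that scale while tests use
much smaller sizes.

What the phantoms deliberately do **not** model: k-space artefacts, coil
bias fields, partial-volume effects, maternal anatomy and pathology-specific
fluid distributions.  Consequently, passing phantom tests demonstrates that
the implementation is correct and that the architecture can learn
shape-versus-intensity discrimination — it says nothing quantitative about
performance on clinical MRI.

## Metrics

All overlap metrics derive from pixel confusion counts with amniotic fluid
as the positive class: Jaccard/IoU `TP/(TP+FP+FN)`, Dice
`2TP/(2TP+FP+FN) = 2J/(J+1)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`.
Two conventions:

* **Empty denominators return 1.**  Slices with no fluid in either mask —
  common at volume edges — count as perfect agreement instead of zeroing
  the dataset mean.  The test suite pins this choice.
* **The soft dice loss** uses raw probabilities in the intersection with a
  smoothing constant `ε = 1e-6` in numerator and denominator, making it
  differentiable and defined for empty masks.

Dataset-level mIoU is the unweighted per-image mean (not a global pixel
pool).  `compare_runs()` applies a two-sided paired Student's t-test to
per-run mIoU vectors; zero-variance differences return p = 1 when the means
agree (and 0 otherwise) rather than erroring.

## Training protocol

`train_config()` encodes the protocol: dice loss, Adagrad at learning rate
0.1 with global-norm gradient clipping, exponential decay
`lr(s) = 0.1 · 0.96^(s/10000)` with a continuous exponent, batches of 8, at
most 200 epochs, and early stopping monitoring validation mean IoU with
patience 10 and baseline 0.75.  Choices the protocol leaves open, fixed
here:

* split unit = **patient volume**, preventing leakage between adjacent
  slices of one sequence; proportions 65/15/20 by largest-remainder
  rounding (45 patients → 29/7/9);
* gradient clipping by global norm at 1.0;
* augmentation contrast semantics: `x' = mean(x) + f · (x - mean(x))` with
  `f ~ U[0.4, 0.6)`, clipped to `[0, 1]`; flips apply identically to image
  and mask;
* "improvement" in early stopping is a strict increase over the best of
  (baseline, all previous epochs).  A run that never beats the baseline
  therefore stops exactly at the patience; a run improving at least once
  per patience window never stops;
* weight initialization is Glorot-uniform from a seeded RNG stream; batch
  norm uses ε = 1e-3 and momentum 0.9 for its running statistics (the
  lower momentum lets evaluation-mode statistics track training within tens
  of steps, which matters at smoke-test scale); Adagrad uses the customary
  initial accumulator of 0.1.

## Numerical and desk-scale choices

The network engine is a tape-based reverse-mode autodiff with compiled
im2col convolution kernels; its gradients are verified against central
finite differences through the complete network in the test suite (relative
error below 1e-4 at randomly probed parameters).

Problem sizes in the tests are chosen so the whole suite runs in minutes on
one CPU: blocks and models are exercised at 16–128 pixels; the capacity
("overfit") test trains each variant on eight noise-free 64×64 phantoms
with quarter-scale filter widths `[4, 8, 16, 32]` (bridge 64) until the
training dice loss falls below 0.1 and training mIoU exceeds 0.9, always
within 200 epochs; the ablation harness runs 3 paired seeds at 32 pixels.
Capacity tests disable early stopping (baseline 2) because their monitored
set is the training set itself and the stopping rule exists for
generalization monitoring.  The full-resolution 512×512 configuration is
exercised for construction, parameter counting and single forward passes,
not for training.

## Known limitations

* Phantoms are a correctness substrate, not a clinical benchmark (above).
* The engine is CPU-only and single-threaded apart from BLAS; training
  full-resolution models is out of its intended scope.
* `"slice"`-unit splitting is provided for completeness but leaks
  correlated neighbouring slices between partitions; patient-level is the
  default for a reason.
* The original max-pool attention variant is implemented as faithfully as
  the family's published descriptions allow, for ablation purposes; small
  undocumented deviations in third-party implementations (e.g. where ReLUs
  sit inside the pyramid) would shift nothing but a few thousand
  parameters.
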