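# afnet

Automatic segmentation of amniotic fluid on T2-weighted fetal MRI, and the
fluid-volume quantification it enables, with **AFNet** — an attention-gated
residual encoder–decoder CNN — implemented end to end in R.

Amniotic fluid volume (AFV) is a key biomarker for gestational disorders
(oligo-/polyhydramnios).  Fluid is bright on T2-weighted sequences, so a
slice-wise binary segmentation turns directly into a volume,
`AFV = Σ mask · dz·dy·dx`, but intensity alone cannot separate fluid from
look-alike structures (bladder, CSF, eyes) — the network must learn shape
and context.  This package is for researchers who want a complete,
desk-scale reproduction of that pipeline: architecture, training protocol,
metrics, volume quantification and a synthetic phantom substrate standing in
for clinical data that cannot be shared.

## The model

Three variants share one skeleton (input `(N, H, W, 1)`, `H, W` divisible
by 8): a stem plus three stride-2 squeeze-and-excitation residual blocks
(8× spatial reduction), an atrous-spatial-pyramid-pooling (ASPP) bridge
(rates 6/12/18), and three decoder stages of attention gate → upsampling →
skip concatenation → residual block, closed by a final ASPP, 1×1
convolution and sigmoid.  The attention gate fuses the encoder skip `E` at
`(2H, 2W)` with the decoder map `D` at `(H, W)`:

    D_out = σ( f( f_s(f(E)) + f(D) ) ) ⊙ D,

where each `f` is a BN→ReLU→3×3-conv unit and `f_s` brings `E` to `(H, W)`
— by 2×2 max pooling in the baseline, or by a stride-2 atrous convolution
in the modified gate.  The variants:

| variant     | attention gate    | decoder upsampling     | parameters |
|-------------|-------------------|------------------------|-----------:|
| `resunetpp` | max-pool          | nearest neighbour      | 4.07 M |
| `afnet_noT` | stride-2 atrous   | nearest neighbour      | 4.85 M |
| `afnet`     | stride-2 atrous   | 2×2 transposed conv    | 4.80 M |

Training follows the reference protocol: soft dice loss, Adagrad at
learning rate 0.1 with global-norm gradient clipping, exponential decay
`lr(s) = 0.1·0.96^(s/10000)`, batch size 8, ≤200 epochs, early stopping on
validation mean IoU (patience 10, baseline 0.75), patient-level 65/15/20
splits, and contrast (`U[0.4, 0.6)`) / flip augmentation.

The CNN engine itself — reverse-mode autodiff on a dynamic tape with
compiled im2col convolution kernels — is part of the package; gradients are
verified against finite differences in the test suite.

## Worked example

Train the full AFNet on eight noise-free 64×64 phantoms until it overfits
them, then quantify a phantom volume:

```r
library(afnet)

cfg <- phantom_config(image_size = 64, n_fluid_blobs = 2, n_confounders = 1,
                      noise_sigma = 0, gradient_strength = 0, seed = 11)
slices <- lapply(1:8, function(i) generate_slice(cfg, seed = 100 + i))
slices[[1]]
#> phantom slice 64x64, fluid pixels: 409 (10.0%)

model <- build_model(model_variant("afnet", filters = c(4, 8, 16, 32),
                                   bridge = 64, input_size = c(64, 64)),
                     seed = 1)
model
#> AFNet-family segmentation network
#>   variant:    afnet
#>   attention:  atrous_modified
#>   upsampling: transpose_conv
#>   filters:    [4, 8, 16, 32] bridge 64
#>   input size: 64x64x1
#>   parameters: 304,045 (0.30 M)

fit <- train_model(model, slices, val_data = slices,
                   config = train_config(max_epochs = 200, baseline = 2,
                                         patience = 1000,
                                         target_loss = 0.095,
                                         target_miou = 0.905),
                   augment = NULL, seed = 1)
fit
#> trained afnet for 37 epoch(s)
#>   final loss 0.0495, best val mIoU 0.9072 at epoch 37

pred <- predict(model, slices[[1]]$image)
metric_report(list(pred$mask[1, , ]), list(slices[[1]]$mask))
#> segmentation metrics over 1 image(s):
#>   mIoU      0.9178 +/- NA
#>   dice      0.9571
#>   precision 0.9327
#>   recall    0.9829

vol <- generate_volume(cfg, 5, voxel_spacing = c(3, 0.8, 0.8))
pv <- predict_volume(model, vol)
pv$volume_ml
#> [1] 1.65   # truth: 1.65 mL
```

The dice loss falls below 0.1 and the training mIoU exceeds 0.9 within 37
epochs here — the capacity check the test suite runs for all three
variants.  The mIoU/dice/precision/recall block is the standard overlap
suite; the volume is the mask voxel count times the voxel volume in mL.
`ablation_study()` repeats seeded training runs per variant on one fixed
split and compares them with paired t-tests, mirroring how the variants are
compared at full scale.

A command-line interface wraps the same functions
(`simulate`, `train`, `predict`, `evaluate`, `overlay`, `ablation`):

```sh
Rscript -e 'quit(status = afnet::cli_main())' simulate \
    --n-patients 2 --size 64 --seed 1 --out phantoms/
```

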