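# mrdbseg

Segmentation of hypoechoic nodules in B-mode thyroid ultrasound is hard:
contrast between a nodule and the surrounding parenchyma is low, boundaries
are blurred by speckle, and the lesion usually occupies a small fraction of
the image. `mrdbseg` implements a dual-branch encoder–decoder network that
attacks these problems by pairing a **visual state-space encoder** (global
context via a four-path 2D selective scan) with a **ResNet-34 encoder**
(local detail), decoding through two asymmetric decoders, and exchanging
features across branches through **cross-skip connections**. The package is
aimed at researchers in medical image analysis who want a fully inspectable,
dependency-light reference implementation: every tensor kernel (convolution,
transpose convolution, selective scan) and the reverse-mode differentiation
used for training are part of the package itself.

## The model

* **Left encoder** — patch-embedding stem (stride 4) and four stages of
  visual state-space blocks (VSSB). Each block layer-normalizes its input
  and runs two parallel branches: linear → depth-wise conv → SiLU → 2D
  selective scan → layer norm (main), and linear → SiLU (gate); the branches
  multiply element-wise, project back, and add the block input. The 2D
  selective scan unrolls the feature map along row-major, column-major and
  both reversed orders, runs each sequence through the input-dependent
  recurrence

  `h_t = exp(Δ_t A) h_{t−1} + Δ_t B_t x_t,  y_t = C_t · h_t + D x_t`

  and sums the four inverse-permuted results.
* **Right encoder** — headless ResNet-34: `y = ReLU(F(x, W) + x)` basic
  blocks with counts 3/4/6/3; for a 256×256 input the stages emit sides
  64/32/16/8 with 64/128/256/512 channels.
* **Decoders** — left: transpose conv → conv → conv (fast resolution
  recovery); right: conv → transpose conv → conv (progressive refinement).
* **Cross-skip** — state-space features are *added* into the right decoder;
  convolutional features are *concatenated* into the left decoder and
  reduced by a 3×3 convolution.
* **Loss** — `L = L_Dice + L_BCE + 0.5 · L_SmoothL1`, the Smooth L1 term
  restricted to the nodule region.
* **Metrics** — DSC, Jaccard (`DSC = 2J/(1+J)`), sensitivity,
  FNR (`= 1 − sensitivity`), boundary HD95, pooled precision–recall AUC.

A deterministic speckle-phantom generator (multiplicative Rayleigh noise,
1–3 blurred hypoechoic ellipses) makes every training and evaluation path
runnable without external data; real datasets are read from the same
`images/*.png` + `masks/*.png` folder layout.

## Worked example

```r
library(mrdbseg)

# 8 phantoms, 64x64, then a reduced-width model trained to overfit them
dir <- file.path(tempdir(), "phantoms")
write_phantom_dataset(dir, 8, phantom_spec(image_side = 64L, seed = 42L))
ds <- load_dataset(dir, 64L)

set.seed(123)
model <- mrdb_init(mrdb_config(input_side = 64L, base_channels = 16L,
                               state_dim = 8L))
cfg <- train_config(learning_rate = 0.001, input_side = 64L, batch_size = 8L,
                    epochs = 300L, seed = 123L, augment = FALSE,
                    early_stop_dsc = 0.95, check_every = 10L)
r <- train_mrdb(model, ds, cfg, verbose = TRUE)
#> epoch 10  loss 1.0637  dsc 0.4689
#> ...
#> epoch 90  loss 0.4705  dsc 0.9497
#> epoch 100  loss 0.4053  dsc 0.9635
```

The log shows the hybrid loss falling from ~1.3 to 0.41 and the train-set
Dice coefficient (threshold 0.5) crossing 0.95 after about 100 Adam steps:
the reduced model memorizes the 8 phantoms, which is the intended sanity
check at desk scale. Evaluation writes the fixed-column CSV report:

```r
evaluate_mrdb(model, ds, out_csv = "report.csv")$summary
# mean DSC/Jaccard/sensitivity/HD95/FNR over images + pooled PR-AUC
```

## Command line

```sh
inst/bin/mrdb phantom --n 100 --out data/ --seed 7
inst/bin/mrdb train   --config cfg.yaml --data data/ --out run/
inst/bin/mrdb eval    --ckpt run/checkpoint.rds --data data/ --out report.csv
inst/bin/mrdb ablate  --config cfg.yaml --data data/
```

`ablate` trains the six cumulative component configurations (single UNet →
dual UNet → +cross-skip → +ResNet-34 → +right decoder → full model) on the
same data and reports loss and Dice per configuration.

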