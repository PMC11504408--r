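---
title: "Model, losses, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, losses, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the network, its training objective, the
evaluation suite and the synthetic data generator are defined, and why the
open design choices were resolved the way they were. It states no empirical
result that the test suite does not itself compute.

## The segmentation problem

B-mode ultrasound of the thyroid shows nodules as (usually) hypoechoic
regions with blurred margins inside speckle-textured parenchyma. Two
failure modes dominate automatic segmentation: purely convolutional models
cannot relate distant image regions (long-range context), and the small
foreground fraction biases pixel losses toward the background. The model
combines a state-space branch for global context with a residual
convolutional branch for local detail, and trains with a loss that
explicitly counterweights class imbalance and boundary error.

## Architecture

**Visual state-space branch.** A 4×4 stride-4 patch embedding brings a
1-channel image of side $S$ to $S/4$; three 2×2 stride-2 patch mergings
then halve resolution and double channels, so the four stage outputs sit at
sides $S/4 \dots S/32$ with channels $C, 2C, 4C, 8C$. Each stage holds
`blocks_per_vss_stage` (default 2) visual state-space blocks. Inside a
block, the input is layer-normalized across channels and processed by two
branches — (a) 1×1 linear to $2C'$, depth-wise 3×3 convolution, SiLU, the
2D selective scan, layer norm; (b) 1×1 linear, SiLU — fused by element-wise
multiplication, projected back to $C'$ channels, and added to the block
input. The residual guarantee (zero output projection ⇒ identity) is tested.

**2D selective scan.** The map is unrolled along four directional paths:
row-major, column-major and their reversals (the convention is fixed and
tested on a 2×2 example). Each sequence runs through an independent
selective state-space recurrence with zero-order-hold discretization
$\bar A_t = \exp(\Delta_t A)$, $\bar B_t = \Delta_t B_t$, where
$\Delta_t, B_t, C_t$ are affine projections of the sequence element and
$A = -\exp(A_{\log})$ is negative, so $|\bar A_t| \le 1$ for any
nonnegative step — an explicit stability invariant. Defaults follow the
conventions of the architecture family this block derives from: state size
16, expansion ratio 2, depth-wise kernel 3, SiLU activations. The parallel
vs sequential evaluation question is moot here: the kernel evaluates the
recurrence sequentially in C++ and is tested against an independent
step-by-step oracle at 1e-4 relative tolerance. The affine projections
carry biases (plain selective-scan formulations often omit them); the
biases default to zero, so the default behaviour is unchanged, but they
make constant-$B$/$C$ configurations expressible, which both the closed-form
tests and degenerate inputs (e.g. all-zero sequences) benefit from. The two
layer normalizations in the block are separate parameter sets.

**Residual branch.** Headless ResNet-34: 7×7 stride-2 stem convolution,
3×3 stride-2 max pool, stages of basic blocks (two 3×3 convolutions with
batch norm, ReLU after the residual addition) with counts 3/4/6/3. The
classification head is removed; the sigmoid the architecture description
places "in the last convolutional layer" is interpreted as the network's
*output* head, not something inside the encoder — a sigmoid in the trunk
would squash features before decoding. The branch consumes 1-channel input
(`in_channels` is configurable). Weights are Kaiming-initialized; there is
a `pretrained` flag but no bundled external weights.

**Decoders and resolution recovery.** Both decoder stage types double the
side and halve the channels; the left order is transpose-conv → conv →
conv, the right is conv → transpose-conv → conv. Upsampling is a learnable
2×2 stride-2 transpose convolution. Four stages from $S/32$ reach only
$S/2$, and the architecture description never states how full resolution
returns; here each decoder carries its own head (one more transpose
convolution plus a 1×1 projection to one logit channel), so each branch
emits a full-resolution map and the fusion step stays trivial.

**Cross-skip and fusion.** Encoder stage $i$ fuses into the decoder
feature at the same spatial resolution (the self-referential index in the
original formulation is read this way and not otherwise interpreted):
state-space features are added into the right decoder (channel counts
match by construction), convolutional features are concatenated into the
left decoder and reduced by a 3×3 convolution. The deepest stages of both
encoders are concatenated and reduced 1×1 to form a single bottleneck
feeding both decoders — sharing gives both decoders global and local
context. The two decoder logit maps are concatenated and reduced by a 1×1
convolution initialized to averaging, then passed through a sigmoid
(an averaging-of-sigmoids mode is available). Output probabilities are
numerically clamped to $(10^{-12}, 1-10^{-12})$ so the open-interval
contract survives double-precision saturation.

**Ablation switches.** `dual_unet`, `csc`, `resnet`, `r_decoder`, `vssb`
reproduce the six cumulative configurations of the component ablation;
disabling a branch substitutes a plain convolutional encoder (or the plain
skip/decoder arrangement) so that "off" rows are honest UNet-style
baselines rather than crippled variants.

## Loss

$L = L_{Dice} + L_{BCE} + 0.5\,L_{SmoothL1}$, computed on soft
probabilities (differentiability decides the soft-vs-hard question for the
Dice masses). BCE clamps predictions to $[10^{-7}, 1-10^{-7}]$. The Smooth
L1 branches are $0.5d^2$ for $d<1$ and $d-0.5$ otherwise — the printed
second branch in the source description lacks the minus sign, and
$d - 0.5$ is the only reading continuous at $d = 1$. Its pixel domain is
the ground-truth foreground (it is described as constraining the nodule
region), falling back to all pixels when the mask is empty; an all-pixels
mode exists. The Dice smoothing constant defaults to 0 with an explicit
both-empty → 0 convention: a nonzero constant would shift small-mask
closed-form values (the 4-pixel half-overlap example must equal exactly
0.5), and with sigmoid outputs the denominator never vanishes in training.

## Metrics

Binarization threshold 0.5. HD95 works on boundary pixels (foreground with
at least one background 4-neighbor, image border counting as background),
Euclidean distances in pixel units, percentile by the linear-interpolation
convention, each directed distance set reduced at the 95th percentile and
the maximum of the two taken. Per-dataset aggregation is the mean over
images; images with an empty mask yield an HD95 of `NA` and are excluded
from the mean. The precision–recall curve pools pixels across the dataset
(per-image averaging was considered and rejected as the default because
pooled curves are what the comparison protocol plots); AUC is trapezoidal
over recall, anchored at recall 0 with the precision of the strictest
threshold, so a constant score map integrates exactly to the foreground
prevalence.

## Synthetic phantoms

The generator emulates the statistical character the model is sensitive
to: a smooth tissue background (Gaussian-filtered noise around mid-gray),
multiplicative Rayleigh speckle of unit mean (`speckle_strength` mixes it
in, default 0.35), and 1–3 hypoechoic ellipses (random center, semi-axes
0.06–0.16 of the side, rotation) darkened by `contrast` (default 0.45)
with their edges blurred (σ = 2.5 px) *in the image only* — the mask stays
the crisp ellipse union. The 1–3 count range reflects that a minority of
clinical images carry more than one nodule; the radius range keeps the
mean foreground fraction below 0.15, emulating the class imbalance that
motivates the Dice term. What the phantoms do **not** model: attenuation
and shadowing, anisotropic speckle, heterogeneous internal echotexture,
neighboring anatomy. A green learning-sanity test therefore establishes
that the architecture, gradients and optimizer work end to end — not
clinical performance.

Augmentations mirror the named training-time transforms — additive noise
(σ ∈ [0.01, 0.05] of dynamic range), histogram equalization, gamma
remapping (γ ∈ [0.7, 1.4]), rectangular cutout (≤ 10% area), and
brightness/contrast jitter — each drawn with probability ½ under a fixed
seed; magnitudes are package defaults since only the transform names are
specified. All are intensity-only, so masks pass through untouched.

## Training and evaluation procedure

Adam at initial rate 0.001, 256×256 inputs, batch 32, 200 epochs are the
configuration defaults; no schedule is applied because only the initial
rate is specified (a schedule hook exists). Loss reduction is the mean
over the batch. For phantom runs an optional 80/20 seed-stable split
selects the best-validation-Dice weights (the epoch-selection question is
resolved as best-checkpoint-keeping); with `val_frac = 0` the final
weights are kept. Training aborts with a diagnostic on non-finite loss.
Evaluation uses batch-norm running moments, making it fully deterministic:
the same checkpoint and data produce byte-identical CSV reports (the
writer formats numbers explicitly and writes in binary mode).

The desk-scale acceptance experiment trains a base-16, 64×64 model on 8
fixed-seed phantoms with at most 300 Adam steps (one full-batch step per
epoch) and requires train-set Dice ≥ 0.95 at threshold 0.5; the threshold
and step budget were fixed before tuning. The five non-full ablation rows
run 25 steps each — enough to assert decreasing loss — because running six
300-step configurations would exceed the suite's runtime budget; the full
configuration's own 300-step run doubles as its ablation row.

## Numerical and engineering notes

All kernels are implemented in the package (C++ via Rcpp/RcppArmadillo:
im2col + BLAS convolutions, transpose convolution as the conv adjoint with
shared kernels, sequential selective scan with backpropagation through
time, fused batch/layer norm) under a small tape-based reverse-mode
autodiff in R. Gradients of every kernel are finite-difference checked in
the test suite. Batch norm uses batch statistics in training and running
moments (momentum 0.1) at inference; layer norm is per-position across
channels. Transpose convolutions use kernel 2, stride 2 — exact doubling,
no overlap artifacts. Checkpoints serialize the configuration plus every
parameter and batch-norm moment and restore bit-identically.

## Known limitations

Pure-R training is desk-scale only (seconds per step at reduced width);
the 256×256/batch-32 default configuration is expressed but not practical
to train here. No multi-class output, no deep supervision, no distributed
training, no physically accurate ultrasound simulation. External clinical
datasets are supported through the folder layout but never required or
bundled.
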