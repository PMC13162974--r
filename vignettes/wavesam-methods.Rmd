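---
title: "wavesam: model, design choices and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wavesam: model, design choices and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wavesam` implements a promptable encoder–decoder segmentation network for
endoscopic polyp images together with its full training procedure, running
entirely on CPU in base R. This vignette documents the model, the choices
that were genuinely open during implementation, and the numerical
conventions the package commits to. The README shows the headline usage;
nothing here states a result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The segmentation problem and the promptable design

Polyps range from sub-5 mm nubs to lesions covering a quarter of the frame,
frequently with boundaries that differ from the surrounding mucosa by only a
few percent in intensity. A *promptable* segmenter receives, besides the
image, a coarse binary hint of the target region and only has to refine it
to pixel accuracy. During training and evaluation the hint is simulated by
iteratively eroding the ground-truth mask and downsampling it to a quarter
resolution (88×88 for 352×352 inputs) — a cheap, reproducible stand-in for
a clinician's rough scribble that deliberately removes boundary detail
while preserving location and rough extent.

Forward model: `ŷ = D(E_i(B(W(I))), E_p(M_p))` with the wavelet
channel-attention block `W` on the raw image, the DSConv-ECA block `B` on
the patch-token grid inside the encoder `E_i`, the prompt encoder `E_p`,
and the mask decoder `D`. Both enhancement blocks are residual and can be
disabled independently (`use_wtca`, `use_dsconv_eca`), which yields the
compressed-baseline ablation.

## Wavelet block: conventions

* **Normalisation.** The Haar transform is implemented in the orthonormal
  convention (1/√2 per 1-D filter, net 1/2 per 2-D level): each 2×2 block
  `[[a,b],[c,d]]` maps to `LL=(a+b+c+d)/2`, `LH=(a−b+c−d)/2`,
  `HL=(a+b−c−d)/2`, `HH=(a−b−c+d)/2`. This conserves energy exactly, makes
  the transform's adjoint equal its inverse (which *is* the backward pass
  used in training), and gives `LL = 2c` for a constant-`c` image.
* **Subband layout.** Channels are blocked by band — all LL channels, then
  LH, HL, HH — so channel attention sees coherent per-band groups.
* **Attention operand.** The recalibration `C′ = C ⊗ A` is applied to the
  *feature-branch output* (1×1 conv → GELU → batch norm → GELU), not to the
  raw subband stack: it is the only reading in which both described
  branches participate in the output. The attention vector itself is
  computed from the raw subband stack's global means.
* **Spatial restoration.** One factor-2 pixel shuffle maps the 4C×(H/2)×(W/2)
  fused tensor exactly back to C×H×W. Two successive factor-2 shuffles
  would overshoot the spatial size, so a single shuffle realises the
  stated (H/2, W/2) → (H, W) restoration.
* **Bottleneck floor.** The attention hidden width is
  `max(ceiling(4C/r), 1)` with r = 16, so the block is well defined at
  C = 3 where 4C/r < 1. At C = 3 the whole block has 375 parameters.
* **Activations.** GELU throughout, with batch norms in the stated
  positions; evaluation mode uses running statistics (momentum 0.1).

## DSConv-ECA block: conventions

* **Composition.** Depthwise k×k (k = 3) → batch norm → GELU → pointwise
  1×1 → batch norm → ECA, plus an identity residual (1×1 projection when
  the channel counts differ). The single pointwise convolution doubles as
  the block's "1×1 convolution": a second, separate 1×1 stage before ECA
  would add ≈0.30 M parameters at C = 384, which is incompatible with the
  +0.16 M parameter delta this block contributes to the published budget,
  so the single-pointwise reading was adopted.
* **Placement.** On the 384-channel 22×22 token grid after patch embedding
  (class token bypasses the block). The alternative image-domain placement
  (3→64 stem before patch embedding) is retained as
  `dsconv_on_image = TRUE` but off by default: a 3→64 stem followed by a
  64-channel patch embedding cannot reproduce the published parameter
  totals, while the grid placement does.
* **ECA kernel rule.** `k = |(log₂C + b)/γ|_odd` with γ = 2, b = 1:
  truncate toward zero, add one if even, floor at 1. This gives k = 1, 3, 5
  at C = 2, 64, 384 and is non-decreasing in C. The 1-D convolution uses
  zero same-padding along the channel axis and carries a bias.

## Encoder, prompt encoder, decoder

The encoder is ViT-S/16 geometry compressed to embedding dimension 384,
depth 6, heads 6 (from 768/12/12), with learnable position embeddings and
a class token that participates in encoding and is dropped before the
decoder. The decoder fuses `F₀ = E_i + E_p + P` elementwise — no
cross-attention tokens; the architecture description is elementwise fusion
followed by two self-attention blocks — where `P` is the parameter-free
2-D sinusoidal encoding: the first d/2 channels encode the 0-based row
coordinate, the last d/2 the column, as interleaved sin/cos pairs with
frequencies `10000^(-2i/d)`. The encoder's learnable and the decoder's
sinusoidal embeddings are asymmetric by design, following the
architecture as described.

"Fivefold upsampling" is realised as four 2× transposed-convolution stages
plus the final 1×1 head (five components): five 2× stages cannot map
22→352, four exactly do. Each stage is transposed conv (k = s = 2) →
channel-wise layer norm → GELU.

**Resolved free widths.** The decoder channel schedule and the prompt
encoder's hidden widths are the architecture's free parameters; they were
resolved once, analytically, so that enumerated parameters and counted
MACs reproduce the published budgets simultaneously:
`decoder_widths = c(384, 192, 96, 48, 24)` and prompt widths `(16, 336)`.
With them the package counts 15,376,814 parameters (15.38 M) for the full
model and 15,223,217 (15.22 M) for the baseline; `count_macs()` gives
9.448 / 9.365 / 9.375 / 9.438 G for full / baseline / +WTCA / +DSConv-ECA.
The default width schedule halves the embedding dimension per stage with a
floor of 8 channels: channel-wise layer norm needs a few channels to
normalise over (with 2 channels it reduces every position to a sign bit),
and the floor only binds for scaled-down configurations — the full
configuration is unaffected.

**MAC counting convention.** `count_macs()` counts one MAC per
multiply-add in convolutions, transposed convolutions, linear layers and
the fixed wavelet filter bank — the layer-level convention of standard
profilers, under which the published per-module deltas are consistent.
Attention score/value matrix products (≈2N²d per block) are excluded by
default and available via `include_attention = TRUE`; normalisations and
activations are not counted. Parameter counts are never formulas: they
enumerate the instantiated arrays.

## Training procedure

* Composite loss `L = λ_d L_dice + λ_b L_bce`, λ_d = λ_b = 1. The Dice
  term uses ε = 1e-6 and sums over the whole batch (batch Dice); the
  per-image variant is exposed through `dice_loss(per_image = TRUE)` and
  used for metrics. BCE is computed from logits in the numerically stable
  form (identical to the probability form).
* Adam (β = 0.9/0.999, ε = 1e-8) with learning rate 1e-4, weight decay
  1e-5 added to the gradient, cosine annealing from the initial rate to 0
  over the run, batch size 8, and global gradient-norm clipping at 1.0
  applied before the moment updates.
* Coarse prompts are regenerated from the (possibly augmented) masks at
  every step with a per-step erosion depth drawn uniformly from 1–5, so
  the prompt channel never leaks the exact target.
* Augmentation: horizontal/vertical flips with probability 0.5 each and
  rotation with probability 0.3, angle uniform in ±15°; the identical
  transform is applied to image (bilinear) and mask (nearest-neighbour,
  border filled with 0), and augmentation is disabled outside training.
* Metrics binarise at probability 0.5. The empty-prediction-vs-empty-truth
  convention scores 1 on all four metrics; an empty denominator against a
  non-empty counterpart scores 0. Per image, Dice = 2·IoU/(1+IoU) holds to
  1e-9 by construction.

## Scaled-down study design

The test suite trains at a reduced configuration: image 64, embedding 32,
depth 2, heads 2, prompt 16 (`test_config()`), 8 synthetic scenes, 300
steps at batch size 8. Two choices define this desk-scale regime:

* **Scene conditions.** Lesion area fractions are drawn from [0.03, 0.2]
  at 64 px: the full-scale generator's lower end (0.002 of the image)
  would be smaller than one cell of the 4×4 latent grid and unrecoverable
  at any training length, which would measure grid resolution rather than
  learning.
* **Learning rate.** 1e-4 is tied to the published full-scale regime of
  ~10⁴ steps; over a 300-step schedule it moves the loss by under 2% for
  any implementation. The scaled run uses 2e-3 with the identical
  Adam/cosine/clipping procedure. The recovery outcome is flat across
  1e-3–3e-3, so the value is a schedule-scaling choice, not a tuned
  threshold. `train_spec()` defaults remain the published constants.

The synthetic generator emulates the *structural* properties the method
responds to — lesion scale variation, weak boundaries (contrast draws
reach below 5%), background texture, specular highlights, exact masks —
but not endoscopy photometry, vignetting, motion blur, instrument
occlusion or inter-patient appearance variation. A passing tiny-overfit
run therefore demonstrates that the architecture, losses, gradients and
optimiser are wired correctly end to end; it does not predict clinical
segmentation accuracy, which requires the public datasets and GPU-scale
training that are outside this package's scope.

## Numerical details and degenerate inputs

* Haar DWT requires even spatial dimensions and raises an error naming the
  offending axis; reconstruction is exact to machine precision and tested
  to 1e-6.
* Erosion treats out-of-image pixels as background, so a full-frame mask
  loses exactly its one-pixel border per pass. An area floor (default 1
  pixel) stops erosion rather than annihilate the foreground; an empty
  ground truth yields an empty prompt with a warning, and the model still
  runs on it.
* Nearest-neighbour downsampling by 4 picks the pixel closest to each
  coarse-cell centre, preserving binarity; bilinear resizing uses the
  half-pixel-centre convention with clamped borders.
* All randomness is seeded: model initialisation (uniform ±1/√fan-in for
  conv/linear layers, truncated normal 0.02 for position/class tokens),
  scene synthesis, erosion depth, batching and augmentation each consume
  an explicitly derived seed, so every run — including PNG fixture
  generation — is bit-reproducible.
* Gradients of every fused backward (convolutions, attention,
  normalisations, losses, the wavelet pair) are validated against central
  finite differences in the test suite.

## Known limitations

* Pure-R execution: a full-configuration forward pass takes seconds, not
  milliseconds; the package targets desk-scale verification and
  small-scale training, not deployment-speed inference.
* Mask prompts only (no point/box prompts, no multi-mask output).
* Single-level Haar decomposition with fixed filters; no learnable or
  non-Haar wavelets.
* Loading ViT-S/16 pre-trained weights is possible through
  `load_state_dict()` name matching but no converter for external
  checkpoint formats is provided; tests use seeded random initialisation.
* Robustness to adversarially bad prompts (e.g. empty or misplaced hints)
  is not modelled beyond the empty-prompt warning path.
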