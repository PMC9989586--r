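---
title: "An attention-guided U-Net for biomedical image segmentation: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An attention-guided U-Net for biomedical image segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`guidedunet` segments binary lesions with a four-stage U-shaped
encoder–decoder. Each encoder stage halves the spatial size (a strided
conv–BN–ReLU followed by two residual blocks) and doubles the channel
count along `base_width * c(1, 2, 4, 8)`; each decoder stage applies two
convolutions and one bilinear 2× upsampling followed by a 1×1
channel-reduction convolution. Arrays are `H × W × C` (the R image
convention, matching `png::readPNG`), with row-major spatial flattening
(`token = (row-1)*W + col`) whenever feature maps become token
matrices.

Three attention modules refine this baseline:

**Progressive enhancement (PEM)** sits at the end of encoding stage 3,
before its output feeds both stage 4 and the skip connection. Branch A
is a 3×3 conv–BN–ReLU; branches B and C are dilated self-attention
convolutions (DSA) at dilation 2 and 3. DSA embeds queries, keys and
values with dilated 3×3 convolutions (padding = dilation, no bias, so
spatial size is preserved), flattens to `n = h·w` tokens, forms the
position-relevance map `B = softmax(M·Nᵀ)` and mixes `B·T`. Two gated
convolutions cascade the branches: `g1 = ReLU(W_f·A) ⊙ σ(W_g·B)`,
`g2 = ReLU(W_f·g1) ⊙ σ(W_g·C)`; since the sigmoid gate lies in (0,1),
each fusion is an elementwise contraction of the embedded feature. The
module output is `ReLU(BN(A + g2))`, a drop-in residual refiner that
keeps the channel plan intact.

**Channel–spatial attention (CSA)** operates on the deepest encoder
feature. The channel stage treats each channel as a token of dimension
`h·w`; no position information is used, because channel identity has no
spatial order. The spatial stage treats each position as a token of
dimension `C` and adds a learned absolute position bias to the logits:
`α_ij = softmax_j(e_ij + p_ij)` with `e_ij = q_i·k_jᵀ/√d` and
`p_ij = v_i·a_ijᵀ` from a trainable table `a` over all flattened
position pairs, shared across heads. Both stages carry residual
connections by default.

**Semantic guidance attention (SGA)** replaces the plain concatenation
on the *second* decoding skip. Decoder stages count from the deepest:
stage 1 consumes the CSA bottleneck and has no skip, so stage 2 is the
first fusion point — and its skip is exactly the PEM-refined encoding
stage 3, pairing the two enhanced streams. The encoder stream supplies
keys and values, the decoder stream queries; channel selection
(`A_w = σ(W·P)` from spatially pooled channel means) reweights K and Q
(not V — only the matching process is re-weighted, not the content
being aggregated); per-head cross-attention `softmax(QKᵀ/√d)·V`
produces the context, which *is* the refined low-level feature and is
concatenated with the decoder stream (`C_low + C_high` channels) before
a 1×1 projection restores the decoder's planned width.

The head is a 1×1 convolution plus sigmoid, giving a per-pixel
foreground probability.

## Objective and metrics

Training minimises `α·L_BCE + β·L_Dice` with `α = β = 0.5` and
`ε = 1e-6`. Two deliberate normalisations:

- **BCE is averaged over pixels** (a sum flag exists). A raw per-pixel
  sum grows with resolution and would swamp the Dice term at 320×320;
  the mean keeps the two terms commensurate at any size.
- **Dice loss defaults to the conventional form**
  `1 − (2Σyp + ε)/(Σy + Σp + ε)`, which is 0 for a perfect prediction.
  The variant without the factor 2 (`dice_form = "printed"`), which
  tends to 0.5 at perfection, is retained behind a switch.

Evaluation uses thresholded confusion counts: Dice `2TP/(2TP+FP+FN)`,
IoU `TP/(TP+FP+FN)` (the Jaccard index — note `dice = 2·iou/(1+iou)`,
so Dice ≥ IoU always), precision and recall. When both masks are empty
(`TP = FP = FN = 0`) all metrics are 1 by convention; a metric whose
denominator vanishes otherwise is 0. Dataset scores (mDice, mIoU) are
per-image metrics averaged over images, not pooled counts — pooling
would let large lesions dominate; per-image averaging weights every
case equally, and the choice is exposed in `evaluate_model()`'s
per-image table.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `base_width` | 16 | channel multiplier; 8 for desk-scale experiments |
| `input_size` | 320×320 | working resolution; must be divisible by 16 |
| `n_heads` | 4 | divides every default channel width and token count |
| DSA heads | 1 | the position-relevance map is a single attention map; heads remain configurable |
| DSA logit scale | off | the dilated-attention map is defined without the `1/√d` factor; a flag turns it on |
| `attention_axis` | `"key"` | see "Numerical choices" |
| `lr0`, schedule | 5e-3, ×0.1 / 40 epochs | standard protocol for this architecture |
| momentum, weight decay | 0.9, 0.001 | weight decay applies to conv/linear weights only, never biases or norms |
| epochs, batch | 300, 4 | full-protocol defaults; short runs override them |
| `loss_config()` | α=β=0.5, ε=1e-6 | combined objective weights |
| threshold | 0.5 | decision threshold for all confusion counts |

## Numerical choices

- **DSA normalisation axis.** The printed softmax denominator of the
  dilated-attention map sums over the *first* index, i.e. normalises
  over queries, which makes `B·T` an un-normalised mixture. The package
  defaults to the self-consistent key-axis reading (each output token's
  mixing weights sum to 1, matching the other attention stages) and
  keeps the printed axis behind `attention_axis = "printed"`.
- **Position bias.** `p_ij = v_i·a_ij` is implemented exactly as
  stated, with the value projection in the position term and a full
  table over flattened position pairs, sized at build time from
  `input_size` and shared across heads. No relative-offset scheme is
  guessed.
- **Residual/projection conventions.** DSA: output projection on,
  residual off (both flags). CSA stages: residuals on. Q/K/V
  projections in CSA and SGA are 1×1 convolutions, i.e. per-token
  linear maps.
- **Upsampling** is bilinear interpolation followed by convolution,
  avoiding transposed-convolution checkerboard artifacts. Bilinear
  resampling uses dense interpolation matrices with half-pixel centres,
  so its adjoint (needed for backpropagation) is exactly the transpose.
- **Initialisation** is Kaiming-normal (`sd = √(2/fan_in)`) with zero
  biases, from a per-model seed; batch-norm starts at identity and
  freezes its running statistics during evaluation.
- **Probabilities are clipped** to `[1e-7, 1−1e-7]` before logarithms.
- **Degenerate inputs**: one-token attention is exactly the value
  projection; zero inputs propagate to zero through PEM (all biases
  start at zero); empty masks follow the metric conventions above.

## The synthetic generator

`generate_synthetic()` emulates the structure that makes lesion
segmentation non-trivial: one to three star-convex blobs (radial
deformation capped at ±25%), bright against the background
(contrast 0.45), boundaries blurred with a Gaussian (σ = 1.5 px),
low-frequency clutter (smoothed noise, amplitude 0.15) and pixel noise
(σ = 0.05), on a 64×64 canvas by default with ~10–30% foreground. The
mask is the *exact pre-blur support*, so ground truth is unambiguous.
Every sample is a pure function of the seed.

What it does *not* emulate: specular highlights, instrument artifacts,
anisotropic texture inside lesions, multi-organ context, or
inter-dataset stain/illumination shift. Passing the test suite
therefore shows that the architecture, gradients, optimisation and
pipeline are correct — not that clinical-grade accuracy transfers to
real endoscopy or histology data, which requires the usual large-scale
training.

## Problem sizes used by the tests

The suite exercises attention oracles at ≤ 8×8 spatial / 16 channels
against explicit double-loop references (tolerance 1e-5), the full
geometry at 320×320 / base width 16, and optimisation at desk scale:
base width 8, 64×64 inputs, eight synthetic images, 200 SGD steps at
learning rate 0.05 without decay — the overfitting oracle. These sizes
were chosen so the whole suite runs on one CPU core in minutes while
still covering every code path; the overfit learning rate is higher
than the full protocol's 5e-3 because memorising eight images in 200
steps is a sanity check of trainability, not a replication of the
300-epoch schedule.

## Known limitations

- Single foreground class; no multi-class head or deep supervision.
- The encoder is a configurable residual network with the four-stage /
  2×-per-stage geometry, not a pretrained ResNet50; no pretrained
  weights exist here, so absolute benchmark scores and absolute FLOP
  figures of full-scale models are out of reach by design — complexity
  accounting targets *orderings* across ablation variants, which are
  scale-invariant.
- Attention is dense: memory and time grow with `(h·w)²` at the
  resolutions where the modules sit (bottleneck and second decoding).
  Windowed or approximate attention is deliberately out of scope.
- The autodiff tape is reverse-mode only, single-threaded apart from
  BLAS, and double precision; it favours correctness and testability
  over speed.
- CVC-style video sequence structure is ignored: frames are independent
  samples.
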