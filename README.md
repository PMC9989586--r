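# guidedunet

Attention-guided transformer U-Net for binary biomedical image
segmentation, in pure R.

Lesions in medical images — polyps in colonoscopy frames, nuclei in
microscopy, melanomas in dermoscopy — vary widely in size and shape,
have blurred boundaries, and sit on cluttered backgrounds. Plain
U-shaped encoder–decoder networks struggle on two fronts: the encoder
extracts weakly discriminative lesion features, and the skip
connections fuse shallow texture with deep semantics across a semantic
gap. This package implements a U-Net variant that attacks both problems
with three transformer-style attention modules:

- **PEM (progressive enhancement module)**, inside the third encoding
  stage: a 3×3 convolution branch and two *dilated self-attention
  convolution* (DSA) branches with dilation rates 2 and 3, fused by a
  cascade of two *gated convolutions*
  `G = ReLU(W_f·F_low) ⊙ σ(W_g·F_high)`, so the larger receptive field
  gates the original feature. DSA computes a position-relevance map
  `B = softmax(M·Nᵀ)` over spatial tokens whose query/key/value
  embeddings are dilated convolutions, and mixes tokens as `B·T`.
- **CSA (channel–spatial attention)**, at the bottleneck: multi-head
  self-attention over *channel* tokens (no position information),
  followed in series by multi-head self-attention over *spatial*
  tokens with a learned absolute position bias
  `p_ij = (x_i W^v)·(a_ij)ᵀ` added to the scaled dot-product logits
  `e_ij = (x_i W^q)(x_j W^k)ᵀ/√d` before the softmax.
- **SGA (semantic guidance attention)**, on the second decoding skip
  connection: *channel selection* `A_w = σ(W·P)` (P = per-channel
  spatial means) reweights the encoder keys and decoder queries, a
  multi-head cross-attention `softmax(QKᵀ/√d)·V` lets the semantic
  stream pick out relevant spatial detail, and the refined context is
  concatenated with the decoder feature.

Training minimises `L = α·L_BCE + β·L_Dice` (α = β = 0.5, ε = 1e-6) by
SGD with momentum 0.9, weight decay 0.001, and a step schedule (initial
learning rate 5e-3, ×0.1 every 40 epochs). Evaluation reports Dice
`2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)`, precision and recall per image.

There is no deep-learning framework underneath: the package ships its
own reverse-mode autodiff tape with compiled (RcppArmadillo) im2col
convolution kernels, so everything installs from source with the
standard scientific R toolchain. A synthetic lesion-image generator
(deformed bright blobs with blurred boundaries on cluttered
backgrounds, exact masks) makes the full pipeline runnable and testable
without any dataset download.

## Worked example

Overfitting a tiny network (base width 8, 64×64 inputs) on eight
synthetic lesion images — 200 SGD steps — demonstrates that every
module trains end to end:

```r
library(guidedunet)
samples <- generate_synthetic(8, synthetic_params(seed = 1))
cfg <- model_config(base_width = 8, input_size = c(64, 64), seed = 1)
tc  <- train_config(lr0 = 0.05, epochs = 100, batch_size = 4,
                    decay_every = 1000, seed = 1, eval_every = 10)
run <- train_model(cfg, samples, cfg = tc)
print(run)
#> <gu_run: 100 epochs, final loss 0.0159, best mDice 0.9914 (epoch 99)>
round(evaluate_model(restore_best(run), samples)$mean, 4)
#>      dice       iou precision    recall
#>    0.9914    0.9829    0.9905    0.9922
complexity(cfg)
#> parameters: 436,689   multiply-accumulates: 23,996,416
```

The training loss falls from 0.84 to 0.016 and the network reproduces
the training masks almost exactly (mDice 0.99) — the expected behaviour
for a segmentation model memorising eight images. `complexity()`
supports ablation studies: disabling `use_pem`, `use_csa` or `use_sga`
strictly reduces both parameter and multiply-accumulate counts, and the
module surfaces (`dsa_forward()`, `pem_forward()`, `csa_forward()`,
`sga_forward()`, `scaled_dot_attention()`, `channel_selection()`,
`gated_conv()`) can each be called on bare arrays.

A command-line interface with `train`, `evaluate`, `synth` and
`complexity` subcommands is installed at
`system.file("scripts", "guidedunet-cli", package = "guidedunet")`.

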