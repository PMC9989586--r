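# Channel-spatial attention at the bottleneck: multi-head self-attention
# over channel tokens (no position information), followed in series by
# multi-head self-attention over spatial-position tokens with a learned
# absolute position bias added to the logits before the softmax.

#' Channel-spatial attention block
#'
#' The channel stage treats each channel as one token of dimension
#' `h * w`; the spatial stage treats each position as one token of
#' dimension `channels` and adds a trainable position bias
#' `p[i,j] = v_i . a[i,j]` (the table `a` is shared across heads) to the
#' scaled dot-product logits. Each stage has a residual connection
#' (`x + attn(x)`) by default.
#'
#' @param channels Channel count of the bottleneck feature.
#' @param n_tokens Number of spatial positions (`h * w`) the block is
#'   sized for; both `channels` and `n_tokens` must be divisible by
#'   `n_heads`.
#' @param n_heads Number of attention heads per stage.
#' @param residual Logical; residual connections around each stage.
#' @return Object of class `gu_csa`.
#' @export
csa_block <- function(channels, n_tokens, n_heads = 4L, residual = TRUE) {
  if (n_tokens %% n_heads != 0)
    stop("csa_block: n_heads must divide n_tokens (h*w) for the channel stage")
  if (channels %% n_heads != 0)
    stop("csa_block: n_heads must divide the channel count for the spatial stage")
  dh <- channels %/% n_heads
  structure(list(
    ch = list(q = make_linear(n_tokens, n_tokens, "csa.ch.q"),
              k = make_linear(n_tokens, n_tokens, "csa.ch.k"),
              v = make_linear(n_tokens, n_tokens, "csa.ch.v"),
              o = make_linear(n_tokens, n_tokens, "csa.ch.o")),
    sp = list(q = make_linear(channels, channels, "csa.sp.q"),
              k = make_linear(channels, channels, "csa.sp.k"),
              v = make_linear(channels, channels, "csa.sp.v"),
              o = make_linear(channels, channels, "csa.sp.o"),
              bias = gu_param(rnorm_arr(c(n_tokens, n_tokens, dh),
                                        sd = 1 / sqrt(dh)),
                              decay = FALSE, name = "csa.sp.bias")),
    channels = channels, n_tokens = n_tokens, n_heads = n_heads,
    residual = residual
  ), class = "gu_csa")
}

# Channel stage on one sample's token matrix node (HW x C).
channel_stage_node <- function(block, tok, record = NULL) {
  ct <- n_transpose(tok)  # C x HW: channel tokens
  st <- block$ch
  q <- linear_node(st$q, ct)
  k <- linear_node(st$k, ct)
  v <- linear_node(st$v, ct)
  dh <- block$n_tokens %/% block$n_heads
  out <- mhsa_node(q, k, v, block$n_heads, 1 / sqrt(dh),
                   record = record, record_key = "channel_attention")
  out <- linear_node(st$o, out)
  out <- n_transpose(out)
  if (isTRUE(block$residual)) n_add(tok, out) else out
}

# Spatial stage on one sample's token matrix node (HW x C).
spatial_stage_node <- function(block, tok, record = NULL) {
  st <- block$sp
  q <- linear_node(st$q, tok)
  k <- linear_node(st$k, tok)
  v <- linear_node(st$v, tok)
  dh <- block$channels %/% block$n_heads
  bias_leaf <- n_leaf(st$bias)
  out <- mhsa_node(q, k, v, block$n_heads, 1 / sqrt(dh),
                   bias_fn = function(vh, h) n_posbias(vh, bias_leaf),
                   record = record, record_key = "spatial_attention")
  out <- linear_node(st$o, out)
  if (isTRUE(block$residual)) n_add(tok, out) else out
}

csa_node <- function(block, x, stage = c("both", "channel", "spatial"),
                     record = NULL) {
  stage <- match.arg(stage)
  d <- dim(x$value)
  outs <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    tok <- n_tokens(x, n)
    if (stage %in% c("both", "channel"))
      tok <- channel_stage_node(block, tok, record)
    if (stage %in% c("both", "spatial"))
      tok <- spatial_stage_node(block, tok, record)
    outs[[n]] <- n_from_tokens(tok, d[1], d[2])
  }
  n_stack(outs)
}

csa_apply <- function(x, block, stage, return_attention = FALSE) {
  x4 <- as_batch(x)
  d <- dim(x4)
  if (is.null(block)) block <- csa_block(d[3], d[1] * d[2])
  record <- if (return_attention) new.env(parent = emptyenv())
  y <- csa_node(block, n_const(x4), stage, record)$value
  if (length(dim(x)) == 3L) y <- array(y, dim(x))
  if (return_attention) {
    list(output = y, attention = as.list(record))
  } else {
    y
  }
}

#' Multi-head self-attention over channel tokens
#'
#' Each channel of the feature map is one token (dimension `h * w`); no
#' position information is used. Shape-preserving.
#'
#' @param x Array `H x W x C` (or batched).
#' @param n_heads Heads used when `block` is `NULL`.
#' @param block Optional pre-built [csa_block()] supplying the projections.
#' @param return_attention Logical; also return the per-head attention
#'   maps (for the last sample processed).
#' @return Array shaped like `x`, or a list with `output` and `attention`.
#' @export
channel_mhsa <- function(x, n_heads = 4L, block = NULL,
                         return_attention = FALSE) {
  if (is.null(block)) {
    d <- dim(as_batch(x))
    block <- csa_block(d[3], d[1] * d[2], n_heads)
  }
  csa_apply(x, block, "channel", return_attention)
}

#' Multi-head self-attention over spatial tokens with position bias
#'
#' Each spatial position is one token (dimension `channels`); a trainable
#' absolute position embedding contributes `p[i,j] = v_i . a[i,j]` to the
#' attention logits before the softmax. Shape-preserving.
#'
#' @inheritParams channel_mhsa
#' @return Array shaped like `x`, or a list with `output` and `attention`.
#' @export
spatial_mhsa <- function(x, n_heads = 4L, block = NULL,
                         return_attention = FALSE) {
  if (is.null(block)) {
    d <- dim(as_batch(x))
    block <- csa_block(d[3], d[1] * d[2], n_heads)
  }
  csa_apply(x, block, "spatial", return_attention)
}

#' Channel-spatial attention forward pass
#'
#' Applies the channel stage then the spatial stage in series. With
#' `enabled = FALSE` the function is the identity (the ablation contract
#' used by the model's `use_csa` switch).
#'
#' @inheritParams channel_mhsa
#' @param enabled Logical ablation switch.
#' @return Array shaped like `x`.
#' @export
csa_forward <- function(x, n_heads = 4L, block = NULL, enabled = TRUE) {
  if (!enabled) return(x)
  if (is.null(block)) {
    d <- dim(as_batch(x))
    block <- csa_block(d[3], d[1] * d[2], n_heads)
  }
  csa_apply(x, block, "both")
}
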