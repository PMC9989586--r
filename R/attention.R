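#' Scaled dot-product multi-head attention
#'
#' Computes standard attention over already-projected token matrices:
#' per head, `A = softmax(q k' / sqrt(d_head) + bias)` and the output is
#' `A %*% v`, with head outputs concatenated along columns. Rows of each
#' attention map are probability vectors (they sum to 1).
#'
#' @param q,k,v Numeric matrices, `n_tokens x dim`. `k` and `v` must share
#'   their token count; `q` may have a different one (cross-attention).
#' @param bias Optional additive logit bias: an `n_q x n_k` matrix applied
#'   to every head, or a 3D array `n_q x n_k x n_heads`.
#' @param n_heads Number of attention heads; must divide `ncol(q)`.
#' @param scale Logit scale; defaults to `1/sqrt(d_head)`. Use `1` for the
#'   unscaled variant.
#' @return A list with `output` (`n_q x dim` matrix) and `attention`
#'   (array `n_q x n_k x n_heads` of attention weights).
#' @examples
#' q <- matrix(rnorm(8), 2, 4)
#' out <- scaled_dot_attention(q, q, q, n_heads = 2)
#' rowSums(out$attention[, , 1])  # each 1
#' @export
scaled_dot_attention <- function(q, k, v, bias = NULL, n_heads = 1L,
                                 scale = NULL) {
  q <- as.matrix(q); k <- as.matrix(k); v <- as.matrix(v)
  d <- ncol(q)
  if (ncol(k) != d || ncol(v) != d)
    stop("scaled_dot_attention: q, k, v must share their embedding dimension")
  if (nrow(k) != nrow(v))
    stop("scaled_dot_attention: k and v must have the same number of tokens")
  if (d %% n_heads != 0)
    stop("scaled_dot_attention: n_heads (", n_heads,
         ") must divide the embedding dimension (", d, ")")
  dh <- d %/% n_heads
  if (is.null(scale)) scale <- 1 / sqrt(dh)
  nq <- nrow(q); nk <- nrow(k)
  out <- matrix(0, nq, d)
  attn <- array(0, c(nq, nk, n_heads))
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    logits <- scale * (q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE]))
    if (!is.null(bias)) {
      logits <- logits + (if (length(dim(bias)) == 3L) bias[, , h] else bias)
    }
    a <- softmax_rows(logits)
    attn[, , h] <- a
    out[, idx] <- a %*% v[, idx, drop = FALSE]
  }
  list(output = out, attention = attn)
}

softmax_rows <- function(x) {
  s <- exp(x - apply(x, 1, max))
  s / rowSums(s)
}

# Graph-side multi-head attention over token-matrix nodes.
#
# qn/kn/vn: nodes holding n x d token matrices (already projected).
# axis: "key" normalises each query's weights over keys (standard);
#       "query" uses the printed axis of the dilated-attention formula,
#       normalising each key's column over queries.
# bias_fn: optional function(v_head_node, head_index) -> logit-bias node.
mhsa_node <- function(qn, kn, vn, n_heads, scale, axis = "key",
                      bias_fn = NULL, record = NULL, record_key = "attention") {
  d <- ncol(qn$value)
  dh <- d %/% n_heads
  heads <- vector("list", n_heads)
  amaps <- if (!is.null(record))
    array(0, c(nrow(qn$value), nrow(kn$value), n_heads))
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    qh <- n_cols(qn, idx)
    kh <- n_cols(kn, idx)
    vh <- n_cols(vn, idx)
    logits <- n_matmul(qh, n_transpose(kh))
    if (scale != 1) logits <- n_scale(logits, scale)
    if (!is.null(bias_fn)) {
      b <- bias_fn(vh, h)
      if (!is.null(b)) logits <- n_add(logits, b)
    }
    a <- if (identical(axis, "query")) n_softmax_cols(logits)
         else n_softmax_rows(logits)
    if (!is.null(record)) amaps[, , h] <- a$value
    heads[[h]] <- n_matmul(a, vh)
  }
  if (!is.null(record)) record[[record_key]] <- amaps
  if (n_heads == 1L) heads[[1L]] else n_cbind(heads)
}

#' Dilated self-attention convolution block
#'
#' Builds the DSA operator: three dilated 3x3 convolutions (no bias)
#' produce query, key and value feature maps; spatial positions are
#' flattened to tokens (row-major) and mixed by a position-relevance
#' attention map `B = softmax(M N')`; the mixed tokens are reshaped back
#' and optionally passed through a 1x1 output projection.
#'
#' By default the attention logits are not scaled by `1/sqrt(d)` and the
#' map is normalised over the key axis so each output token's mixing
#' weights sum to 1; `axis = "query"` selects normalisation over queries
#' instead (the un-normalised-mixture reading), and `scale = TRUE` turns
#' the `1/sqrt(d)` factor on.
#'
#' @param channels Channel count of the feature the block operates on.
#' @param dilation Positive integer dilation rate of the q/k/v convolutions;
#'   padding is chosen as `dilation` so spatial size is preserved.
#' @param n_heads Heads over the channel dimension (default 1: a single
#'   position-relevance map).
#' @param scale Logical; apply the `1/sqrt(d_head)` logit scale.
#' @param axis `"key"` or `"query"` softmax normalisation axis.
#' @param out_proj Logical; apply a 1x1 output projection.
#' @param residual Logical; add the input back to the output.
#' @return An object of class `gu_dsa`.
#' @export
dsa_block <- function(channels, dilation = 2L, n_heads = 1L, scale = FALSE,
                      axis = c("key", "query"), out_proj = TRUE,
                      residual = FALSE) {
  if (dilation < 1) stop("dsa_block: dilation must be a positive integer")
  if (channels %% n_heads != 0)
    stop("dsa_block: n_heads must divide the channel count")
  axis <- match.arg(axis)
  structure(list(
    q = make_conv(channels, channels, 3L, pad = dilation, dil = dilation,
                  bias = FALSE, name = "dsa.q"),
    k = make_conv(channels, channels, 3L, pad = dilation, dil = dilation,
                  bias = FALSE, name = "dsa.k"),
    v = make_conv(channels, channels, 3L, pad = dilation, dil = dilation,
                  bias = FALSE, name = "dsa.v"),
    proj = if (out_proj) make_conv(channels, channels, 1L, pad = 0L,
                                   name = "dsa.proj"),
    channels = channels, dilation = dilation, n_heads = n_heads,
    scale = scale, axis = axis, residual = residual
  ), class = "gu_dsa")
}

dsa_node <- function(block, x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; N <- d[4]
  qf <- conv_node(block$q, x)
  kf <- conv_node(block$k, x)
  vf <- conv_node(block$v, x)
  sc <- if (isTRUE(block$scale)) 1 / sqrt(block$channels / block$n_heads) else 1
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    mixed <- mhsa_node(n_tokens(qf, n), n_tokens(kf, n), n_tokens(vf, n),
                       block$n_heads, sc, axis = block$axis)
    outs[[n]] <- n_from_tokens(mixed, H, W)
  }
  y <- n_stack(outs)
  if (!is.null(block$proj)) y <- conv_node(block$proj, y)
  if (isTRUE(block$residual)) y <- n_add(y, x)
  y
}

#' Apply a dilated self-attention convolution to a feature map
#'
#' Functional front end to [dsa_block()]: runs the forward pass on a single
#' `H x W x C` feature map and returns a feature map of identical shape.
#' If `block` is omitted a freshly initialised block (random weights) is
#' created, which is useful for shape/contract checks.
#'
#' @param x Numeric array `H x W x C` (or `H x W x C x N` batch).
#' @param dilation Dilation rate used when `block` is `NULL`.
#' @param block Optional pre-built [dsa_block()].
#' @param ... Passed to [dsa_block()] when one is created.
#' @return Array with the same shape as `x`.
#' @export
dsa_forward <- function(x, dilation = 2L, block = NULL, ...) {
  x4 <- as_batch(x)
  if (is.null(block)) block <- dsa_block(dim(x4)[3], dilation, ...)
  y <- dsa_node(block, n_const(x4))$value
  if (length(dim(x)) == 3L) array(y, dim(x)) else y
}

# Promote H x W x C to H x W x C x 1.
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected an H x W x C (or H x W x C x N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}
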