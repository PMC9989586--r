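# Semantic guidance attention on the second decoding skip connection.
# The low-level encoder stream supplies keys and values, the high-level
# decoder stream supplies queries; channel selection re-weights K and Q;
# multi-head cross-attention aggregates the values, and the refined
# low-level context is concatenated with the high-level feature.

#' Channel selection
#'
#' Computes per-channel spatial means `P`, mixes them through a learned
#' square matrix and squashes with a sigmoid to channel weights
#' `A_w = sigmoid(W P)` in (0,1), then rescales each channel of the input:
#' `F~ = A_w . F`.
#'
#' @param f Array `H x W x C`.
#' @param w Numeric `C x C` mixing matrix.
#' @return List with `output` (rescaled feature, same shape as `f`) and
#'   `weights` (numeric vector of length `C`, entries strictly in (0,1)).
#' @export
channel_selection <- function(f, w) {
  d <- dim(f)
  if (length(d) != 3L) stop("channel_selection: f must be H x W x C")
  C <- d[3]
  w <- as.matrix(w)
  if (!all(dim(w) == c(C, C)))
    stop("channel_selection: w must be ", C, " x ", C)
  p <- apply(f, 3, mean)
  a <- as.vector(1 / (1 + exp(-(w %*% p))))
  out <- f * rep(a, each = d[1] * d[2])
  list(output = out, weights = a)
}

#' Semantic guidance attention block
#'
#' @param c_low,c_high Channel counts of the encoder (low-level) and
#'   decoder (high-level) streams.
#' @param n_heads Cross-attention heads.
#' @param embed Common embedding dimension for the Q/K/V projections
#'   (1x1 convolutions); defaults to `c_low`.
#' @param out_channels Channel count after the post-concatenation 1x1
#'   projection; defaults to `c_low + c_high` (the decoder's planned
#'   width for a plain concatenation skip).
#' @return Object of class `gu_sga`.
#' @export
sga_block <- function(c_low, c_high, n_heads = 4L, embed = c_low,
                      out_channels = c_low + c_high) {
  if (embed %% n_heads != 0)
    stop("sga_block: n_heads must divide the embedding dimension")
  structure(list(
    pk = make_conv(c_low, embed, 1L, pad = 0L, name = "sga.k"),
    pv = make_conv(c_low, embed, 1L, pad = 0L, name = "sga.v"),
    pq = make_conv(c_high, embed, 1L, pad = 0L, name = "sga.q"),
    cs_k = gu_param(matrix(stats::rnorm(embed * embed, sd = 1 / sqrt(embed)),
                           embed, embed), name = "sga.cs_k"),
    cs_q = gu_param(matrix(stats::rnorm(embed * embed, sd = 1 / sqrt(embed)),
                           embed, embed), name = "sga.cs_q"),
    post = make_conv(embed + c_high, out_channels, 1L, pad = 0L,
                     name = "sga.post"),
    c_low = c_low, c_high = c_high, embed = embed, n_heads = n_heads,
    out_channels = out_channels
  ), class = "gu_sga")
}

# Channel selection on a token-matrix node using a weight-matrix param.
cs_node <- function(tok, w_param) {
  a <- n_sigmoid(n_matvec(n_leaf(w_param), n_colmeans(tok)))
  n_scale_cols(tok, a)
}

# Returns the post-projection node; the pre-projection concatenation is
# stored in `record$sga_concat` when a record environment is supplied.
sga_node <- function(block, low, high, record = NULL) {
  dl <- dim(low$value)
  dh2 <- dim(high$value)
  if (!identical(dl[1:2], dh2[1:2]))
    stop("sga: low and high streams must share spatial size")
  H <- dl[1]; W <- dl[2]; N <- dl[4]
  kf <- conv_node(block$pk, low)
  vf <- conv_node(block$pv, low)
  qf <- conv_node(block$pq, high)
  dh <- block$embed %/% block$n_heads
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    ktok <- cs_node(n_tokens(kf, n), block$cs_k)
    qtok <- cs_node(n_tokens(qf, n), block$cs_q)
    vtok <- n_tokens(vf, n)
    ctx <- mhsa_node(qtok, ktok, vtok, block$n_heads, 1 / sqrt(dh),
                     record = record, record_key = "cross_attention")
    outs[[n]] <- n_from_tokens(ctx, H, W)
  }
  ctx4 <- n_stack(outs)
  cat4 <- n_concat_c(ctx4, high)
  if (!is.null(record)) record$sga_concat <- cat4$value
  conv_node(block$post, cat4)
}

#' Semantic guidance attention forward pass
#'
#' Fuses an encoder (low-level) and a decoder (high-level) feature of
#' equal spatial size. Channel selection is applied to K and Q, the
#' cross-attention context refines the low-level stream, and the context
#' is concatenated with the high-level stream (channels
#' `embed + c_high`) before the optional 1x1 output projection.
#'
#' @param low,high Arrays `H x W x C_low` and `H x W x C_high` (or
#'   batched 4D).
#' @param block Optional pre-built [sga_block()].
#' @param n_heads Heads used when `block` is `NULL`.
#' @param project Logical; apply the post-concatenation 1x1 projection.
#'   With `FALSE` the raw concatenation (channels `embed + c_high`) is
#'   returned, exposing the concatenation contract.
#' @return Fused feature array.
#' @export
sga_forward <- function(low, high, block = NULL, n_heads = 4L,
                        project = TRUE) {
  l4 <- as_batch(low)
  h4 <- as_batch(high)
  if (is.null(block))
    block <- sga_block(dim(l4)[3], dim(h4)[3], n_heads)
  record <- new.env(parent = emptyenv())
  out <- sga_node(block, n_const(l4), n_const(h4), record)$value
  if (!project) out <- record$sga_concat
  if (length(dim(low)) == 3L) out <- array(out, dim(out)[1:3])
  out
}
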