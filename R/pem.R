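# Progressive enhancement module: a 3x3 convolution branch plus two
# dilated self-attention convolution branches (dilation 2 and 3) fused by
# a cascade of two gated convolutions, so the larger receptive field
# guides the discriminative extraction of the original feature.

#' Gated convolution parameter set
#'
#' Convolution kernels producing the sigmoid gate (from the large
#' receptive-field input) and the ReLU feature embedding (from the small
#' receptive-field input). Kernels default to 1x1, i.e. per-pixel
#' channel-mixing embedding matrices.
#'
#' @param c_high,c_low Channel counts of the gate source and embedding
#'   source features.
#' @param c_out Common output channel count.
#' @param k Kernel size (odd).
#' @return A list of class `gu_gate_params` with elements `w_g`, `b_g`,
#'   `w_f`, `b_f` (plain numeric arrays).
#' @export
gate_params <- function(c_high, c_low, c_out = c_low, k = 1L) {
  sd_g <- sqrt(2 / (k * k * c_high))
  sd_f <- sqrt(2 / (k * k * c_low))
  structure(list(
    w_g = rnorm_arr(c(k, k, c_high, c_out), sd_g), b_g = numeric(c_out),
    w_f = rnorm_arr(c(k, k, c_low, c_out), sd_f), b_f = numeric(c_out),
    k = k
  ), class = "gu_gate_params")
}

#' Gated convolution
#'
#' Fuses a large receptive-field feature (`f_high`, the gate source) with a
#' small receptive-field feature (`f_low`, the embedding source):
#' `G = ReLU(W_f * F_low) . sigmoid(W_g * F_high)`, elementwise. The
#' sigmoid gate lies in (0,1), so the output is an elementwise contraction
#' of the embedded feature.
#'
#' @param f_high,f_low Numeric arrays `H x W x C` sharing spatial size.
#' @param params A [gate_params()] set whose input channel counts match.
#' @return Array `H x W x c_out`.
#' @export
gated_conv <- function(f_high, f_low, params) {
  dh <- dim(f_high); dl <- dim(f_low)
  if (!identical(dh[1:2], dl[1:2]))
    stop("gated_conv: f_high and f_low must share spatial size")
  hb <- as_batch(f_high); lb <- as_batch(f_low)
  pad <- (params$k - 1L) %/% 2L
  gate <- conv2d_fwd_cpp(hb, params$w_g, params$b_g, 1L, pad, 1L)
  emb <- conv2d_fwd_cpp(lb, params$w_f, params$b_f, 1L, pad, 1L)
  y <- pmax(emb, 0) * (1 / (1 + exp(-gate)))
  array(y, dim(y)[1:3])
}

make_gc <- function(c_high, c_low, c_out = c_low, name = "gc") {
  structure(list(
    g = make_conv(c_high, c_out, 1L, pad = 0L, name = paste0(name, ".g")),
    f = make_conv(c_low, c_out, 1L, pad = 0L, name = paste0(name, ".f"))
  ), class = "gu_gc")
}

gc_node <- function(layer, f_high, f_low) {
  n_mul(n_relu(conv_node(layer$f, f_low)),
        n_sigmoid(conv_node(layer$g, f_high)))
}

#' Progressive enhancement module block
#'
#' Branch A is a plain 3x3 convolution (BN + ReLU); branches B and C are
#' dilated self-attention convolutions with dilation rates 2 and 3. The
#' first gated convolution uses B as gate source and A as embedding; the
#' second uses C as gate source and the first gate's output as embedding.
#' The final output is `ReLU(BN(A + g2))`, so the module is a drop-in
#' residual refiner that preserves the channel count.
#'
#' @param channels Channel count the module operates on.
#' @param dsa_heads,dsa_scale,dsa_axis,dsa_residual Options forwarded to
#'   [dsa_block()].
#' @return Object of class `gu_pem`.
#' @export
pem_block <- function(channels, dsa_heads = 1L, dsa_scale = FALSE,
                      dsa_axis = "key", dsa_residual = FALSE) {
  structure(list(
    a = make_cbr(channels, channels, 3L, name = "pem.a"),
    dsa2 = dsa_block(channels, 2L, dsa_heads, dsa_scale, dsa_axis,
                     residual = dsa_residual),
    dsa3 = dsa_block(channels, 3L, dsa_heads, dsa_scale, dsa_axis,
                     residual = dsa_residual),
    gc1 = make_gc(channels, channels, channels, "pem.gc1"),
    gc2 = make_gc(channels, channels, channels, "pem.gc2"),
    bn = make_bn(channels, "pem.bn"),
    channels = channels
  ), class = "gu_pem")
}

pem_node <- function(block, x, training) {
  a <- cbr_node(block$a, x, training)
  b <- dsa_node(block$dsa2, x)
  c3 <- dsa_node(block$dsa3, x)
  g1 <- gc_node(block$gc1, f_high = b, f_low = a)
  g2 <- gc_node(block$gc2, f_high = c3, f_low = g1)
  n_relu(bn_node(block$bn, n_add(a, g2), training))
}

#' Run the progressive enhancement module on a feature map
#'
#' @param x Numeric array `H x W x C` (or batched `H x W x C x N`).
#' @param block Optional pre-built [pem_block()]; a freshly initialised one
#'   is created otherwise.
#' @param training Logical; batch statistics (TRUE) or running statistics
#'   (FALSE) in the batch-norm layers.
#' @return Array with the same shape as `x`.
#' @export
pem_forward <- function(x, block = NULL, training = FALSE) {
  x4 <- as_batch(x)
  if (is.null(block)) block <- pem_block(dim(x4)[3])
  y <- pem_node(block, n_const(x4), training)$value
  if (length(dim(x)) == 3L) array(y, dim(x)) else y
}
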