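# Layer constructors. A layer is a plain list tagged with a class; its
# trainable parameters are `gu_param` environments so that one flat
# parameter list can drive the optimiser. Batch-norm running statistics
# live in a `state` environment (mutated during training, frozen at eval).

rnorm_arr <- function(dims, sd) array(stats::rnorm(prod(dims), sd = sd), dims)

#' @keywords internal
make_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                      dil = 1L, bias = TRUE, name = "conv") {
  if (dil > 1L && missing(pad)) pad <- dil * (k - 1L) %/% 2L
  # Kaiming/He initialisation for ReLU networks: sd = sqrt(2 / fan_in)
  sd <- sqrt(2 / (k * k * cin))
  w <- gu_param(rnorm_arr(c(k, k, cin, cout), sd), decay = TRUE,
                name = paste0(name, ".w"))
  b <- if (bias) gu_param(numeric(cout), decay = FALSE, name = paste0(name, ".b"))
  structure(list(w = w, b = b, k = k, stride = stride, pad = pad, dil = dil,
                 cin = cin, cout = cout),
            class = "gu_conv")
}

conv_node <- function(layer, x) {
  n_conv2d(x, n_leaf(layer$w),
           if (!is.null(layer$b)) n_leaf(layer$b),
           stride = layer$stride, pad = layer$pad, dil = layer$dil)
}

#' @keywords internal
make_bn <- function(c, name = "bn") {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(c)
  state$running_var <- rep(1, c)
  structure(list(gamma = gu_param(rep(1, c), decay = FALSE,
                                  name = paste0(name, ".gamma")),
                 beta = gu_param(numeric(c), decay = FALSE,
                                 name = paste0(name, ".beta")),
                 state = state, c = c),
            class = "gu_bn")
}

bn_node <- function(layer, x, training) {
  n_bn(x, n_leaf(layer$gamma), n_leaf(layer$beta), layer$state, training)
}

#' @keywords internal
make_linear <- function(din, dout, name = "lin") {
  sd <- sqrt(2 / din)
  structure(list(w = gu_param(matrix(stats::rnorm(din * dout, sd = sd), din, dout),
                              decay = TRUE, name = paste0(name, ".w")),
                 din = din, dout = dout),
            class = "gu_linear")
}

linear_node <- function(layer, tok) n_matmul(tok, n_leaf(layer$w))

# conv -> BN -> ReLU block, the encoder/decoder workhorse
make_cbr <- function(cin, cout, k = 3L, stride = 1L, dil = 1L, name = "cbr") {
  structure(list(conv = make_conv(cin, cout, k, stride,
                                  pad = dil * (k - 1L) %/% 2L, dil = dil,
                                  bias = FALSE, name = name),
                 bn = make_bn(cout, name = paste0(name, ".bn"))),
            class = "gu_cbr")
}

cbr_node <- function(layer, x, training) {
  n_relu(bn_node(layer$bn, conv_node(layer$conv, x), training))
}

# Pre-activation-free residual block: conv-BN-ReLU-conv-BN + identity, ReLU.
make_resblock <- function(c, name = "rb") {
  structure(list(c1 = make_conv(c, c, 3L, bias = FALSE, name = paste0(name, ".c1")),
                 b1 = make_bn(c, paste0(name, ".b1")),
                 c2 = make_conv(c, c, 3L, bias = FALSE, name = paste0(name, ".c2")),
                 b2 = make_bn(c, paste0(name, ".b2"))),
            class = "gu_resblock")
}

resblock_node <- function(layer, x, training) {
  h <- n_relu(bn_node(layer$b1, conv_node(layer$c1, x), training))
  h <- bn_node(layer$b2, conv_node(layer$c2, h), training)
  n_relu(n_add(h, x))
}

# Recursively harvest every gu_param inside a nested layer structure.
#' @keywords internal
collect_params <- function(x) {
  if (inherits(x, "gu_param")) return(list(x))
  if (is.list(x)) {
    out <- list()
    for (el in x) {
      if (!is.null(el)) out <- c(out, collect_params(el))
    }
    return(out)
  }
  list()
}

# Harvest batch-norm state environments (for checkpointing).
#' @keywords internal
collect_bn_states <- function(x) {
  if (inherits(x, "gu_bn")) return(list(x$state))
  if (inherits(x, "gu_param")) return(list())
  if (is.list(x)) {
    out <- list()
    for (el in x) {
      if (!is.null(el)) out <- c(out, collect_bn_states(el))
    }
    return(out)
  }
  list()
}
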