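# Full network assembly: residual encoder with four 2x-downsampling
# stages, progressive enhancement inside the third encoding, channel-
# spatial attention at the bottleneck, and a U-Net decoder (two
# convolutions + one upsampling per stage) whose second stage fuses the
# PEM-refined skip through semantic guidance attention. Decoder stages
# count from the deepest: stage 1 consumes the bottleneck and has no
# skip; stages 2-4 fuse encoder skips e3/e2/e1.

#' Model configuration
#'
#' @param in_channels Input image channels (grayscale inputs are
#'   replicated to 3 by the data pipeline; default 3).
#' @param base_width Channel multiplier; encoder stages use
#'   `base_width * c(1, 2, 4, 8)`.
#' @param n_heads Heads for the bottleneck and skip attention modules.
#' @param input_size `c(height, width)`, each divisible by 16 (four 2x
#'   downsamplings).
#' @param use_pem,use_csa,use_sga Ablation switches for the three
#'   attention modules.
#' @param dsa_heads,dsa_scale,dsa_residual Dilated self-attention
#'   options (see [dsa_block()]).
#' @param attention_axis `"key"` (weights of each output token sum to 1)
#'   or `"printed"` (normalisation over the query axis) for the dilated
#'   self-attention maps.
#' @param csa_residual Residual connections around the two bottleneck
#'   attention stages.
#' @param seed Integer seed for weight initialisation.
#' @return List of class `gu_config`.
#' @export
model_config <- function(in_channels = 3L, base_width = 16L, n_heads = 4L,
                         input_size = c(320L, 320L), use_pem = TRUE,
                         use_csa = TRUE, use_sga = TRUE, dsa_heads = 1L,
                         dsa_scale = FALSE, dsa_residual = FALSE,
                         attention_axis = c("key", "printed"),
                         csa_residual = TRUE, seed = 1L) {
  attention_axis <- match.arg(attention_axis)
  input_size <- as.integer(input_size)
  if (any(input_size %% 16L != 0L))
    stop("model_config: input_size must be divisible by 16 ",
         "(four 2x downsamplings)")
  if (base_width < 1L) stop("model_config: base_width must be >= 1")
  n_bottleneck <- prod(input_size %/% 16L)
  if (n_bottleneck %% n_heads != 0L || (8L * base_width) %% n_heads != 0L ||
      (4L * base_width) %% n_heads != 0L)
    stop("model_config: n_heads must divide the bottleneck token count ",
         "and the deep channel widths")
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 n_heads = as.integer(n_heads), input_size = input_size,
                 use_pem = isTRUE(use_pem), use_csa = isTRUE(use_csa),
                 use_sga = isTRUE(use_sga), dsa_heads = as.integer(dsa_heads),
                 dsa_scale = isTRUE(dsa_scale),
                 dsa_residual = isTRUE(dsa_residual),
                 attention_axis = attention_axis,
                 csa_residual = isTRUE(csa_residual), seed = as.integer(seed)),
            class = "gu_config")
}

#' Build the segmentation network
#'
#' @param config A [model_config()].
#' @return Object of class `guided_unet` holding the layer tree, a flat
#'   parameter list and the configuration.
#' @export
build_model <- function(config = model_config()) {
  w <- config$base_width
  cs <- w * c(1L, 2L, 4L, 8L)
  hs <- config$input_size[1] %/% c(2L, 4L, 8L, 16L)
  ws <- config$input_size[2] %/% c(2L, 4L, 8L, 16L)
  dsa_axis <- if (config$attention_axis == "printed") "query" else "key"
  model <- with_seed(config$seed, {
    enc <- list()
    cin <- config$in_channels
    for (s in 1:4) {
      enc[[s]] <- list(down = make_cbr(cin, cs[s], 3L, stride = 2L,
                                       name = sprintf("enc%d.down", s)),
                       rb1 = make_resblock(cs[s], sprintf("enc%d.rb1", s)),
                       rb2 = make_resblock(cs[s], sprintf("enc%d.rb2", s)))
      cin <- cs[s]
    }
    pem <- if (config$use_pem)
      pem_block(cs[3], config$dsa_heads, config$dsa_scale, dsa_axis,
                config$dsa_residual)
    csa <- if (config$use_csa)
      csa_block(cs[4], hs[4] * ws[4], config$n_heads, config$csa_residual)
    sga <- if (config$use_sga)
      sga_block(cs[3], cs[3], config$n_heads, embed = cs[3],
                out_channels = 2L * cs[3])
    dec <- list(
      list(c1 = make_cbr(cs[4], cs[4], name = "dec1.c1"),
           c2 = make_cbr(cs[4], cs[4], name = "dec1.c2"),
           red = make_cbr(cs[4], cs[3], k = 1L, name = "dec1.red")),
      list(c1 = make_cbr(2L * cs[3], cs[3], name = "dec2.c1"),
           c2 = make_cbr(cs[3], cs[3], name = "dec2.c2"),
           red = make_cbr(cs[3], cs[2], k = 1L, name = "dec2.red")),
      list(c1 = make_cbr(2L * cs[2], cs[2], name = "dec3.c1"),
           c2 = make_cbr(cs[2], cs[2], name = "dec3.c2"),
           red = make_cbr(cs[2], cs[1], k = 1L, name = "dec3.red")),
      list(c1 = make_cbr(2L * cs[1], cs[1], name = "dec4.c1"),
           c2 = make_cbr(cs[1], cs[1], name = "dec4.c2"),
           red = make_cbr(cs[1], cs[1], k = 1L, name = "dec4.red"))
    )
    head <- make_conv(cs[1], 1L, 1L, pad = 0L, name = "head")
    list(enc = enc, pem = pem, csa = csa, sga = sga, dec = dec, head = head)
  })
  model$config <- config
  model$params <- collect_params(model[c("enc", "pem", "csa", "sga",
                                         "dec", "head")])
  model$bn_states <- collect_bn_states(model[c("enc", "pem", "csa", "sga",
                                               "dec", "head")])
  class(model) <- "guided_unet"
  model
}

# Forward pass on an H x W x C x N batch node. `record`, when an
# environment, receives named intermediate feature values.
forward_net <- function(model, x, training = FALSE, record = NULL) {
  cfg <- model$config
  keep <- function(name, node) {
    if (!is.null(record)) record[[name]] <- node$value
    node
  }
  h <- x
  skips <- list()
  for (s in 1:4) {
    st <- model$enc[[s]]
    h <- cbr_node(st$down, h, training)
    h <- resblock_node(st$rb1, h, training)
    h <- resblock_node(st$rb2, h, training)
    if (s == 3L && cfg$use_pem) {
      keep("pem_in", h)
      h <- keep("pem_out", pem_node(model$pem, h, training))
    }
    keep(paste0("enc", s), h)
    skips[[s]] <- h
  }
  if (cfg$use_csa) h <- csa_node(model$csa, h)
  keep("csa", h)
  # decoder stage 1: two convolutions + one upsampling, no skip
  d <- model$dec[[1]]
  h <- cbr_node(d$c2, cbr_node(d$c1, h, training), training)
  h <- cbr_node(d$red, n_upsample2(h), training)
  keep("dec1", h)
  # stage 2: SGA (or plain concatenation) with the PEM-refined e3 skip
  if (cfg$use_sga) {
    fused <- sga_node(model$sga, skips[[3]], h, record)
  } else {
    fused <- n_concat_c(skips[[3]], h)
    if (!is.null(record)) record$sga_concat <- fused$value
  }
  d <- model$dec[[2]]
  h <- cbr_node(d$c2, cbr_node(d$c1, fused, training), training)
  h <- cbr_node(d$red, n_upsample2(h), training)
  keep("dec2", h)
  for (s in 3:4) {
    d <- model$dec[[s]]
    h <- n_concat_c(skips[[5L - s]], h)
    h <- cbr_node(d$c2, cbr_node(d$c1, h, training), training)
    h <- cbr_node(d$red, n_upsample2(h), training)
    keep(paste0("dec", s), h)
  }
  prob <- n_sigmoid(conv_node(model$head, h))
  keep("prob", prob)
  prob
}

#' Predict probability maps
#'
#' @param object A `guided_unet` model.
#' @param x A [seg_sample()], a list of them, an `H x W x C` array or an
#'   `H x W x C x N` batch; spatial size must equal the configured
#'   `input_size` (use [resize_sample()] otherwise).
#' @param ... Unused.
#' @return `H x W x N` array of probabilities in \[0,1\].
#' @export
predict.guided_unet <- function(object, x, ...) {
  x4 <- batch_from(x, object$config)
  p <- forward_net(object, n_const(x4), training = FALSE)$value
  array(p, dim(p)[c(1, 2, 4)])
}

batch_from <- function(x, config) {
  if (inherits(x, "seg_sample")) x <- list(x)
  if (is.list(x)) {
    imgs <- lapply(x, `[[`, "image")
    x <- array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
  }
  x4 <- as_batch(x)
  d <- dim(x4)
  if (!identical(d[1:2], as.integer(config$input_size)))
    stop("input is ", d[1], "x", d[2], " but the model was built for ",
         config$input_size[1], "x", config$input_size[2],
         "; resize with resize_sample() first")
  if (d[3] != config$in_channels)
    stop("input has ", d[3], " channels; model expects ",
         config$in_channels)
  x4
}

#' Dump intermediate feature maps
#'
#' Runs a forward pass on one image and returns the requested named
#' intermediate features (encoder/decoder stages, PEM input/output,
#' bottleneck attention output, the pre-projection SGA concatenation and
#' the final probability map).
#'
#' @param model A `guided_unet`.
#' @param image `H x W x C` array or [seg_sample()].
#' @param stages Character vector from `enc1..enc4`, `pem_in`, `pem_out`,
#'   `csa`, `dec1..dec4`, `sga_concat`, `prob`.
#' @return Named list of `H x W x C` arrays.
#' @export
dump_feature_maps <- function(model, image,
                              stages = c("dec1", "dec2", "dec3", "dec4")) {
  valid <- c(paste0("enc", 1:4), "pem_in", "pem_out", "csa",
             paste0("dec", 1:4), "sga_concat", "prob")
  bad <- setdiff(stages, valid)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         " — valid: ", paste(valid, collapse = ", "))
  record <- new.env(parent = emptyenv())
  x4 <- batch_from(image, model$config)
  forward_net(model, n_const(x4), training = FALSE, record = record)
  out <- lapply(stages, function(s) {
    v <- record[[s]]
    if (is.null(v))
      stop("stage '", s, "' was not produced (module disabled in config)")
    array(v, dim(v)[1:3])
  })
  names(out) <- stages
  out
}

#' Parameter and multiply-accumulate counts
#'
#' Parameters are counted exactly by walking the built model; MACs are
#' accumulated layer by layer at the configured input size (convolutions
#' `k^2 * C_in * C_out * H_out * W_out`, attention `n^2 * d` per map, and
#' the corresponding projection products).
#'
#' @param config A [model_config()] or an already-built `guided_unet`.
#' @return List of class `gu_complexity` with `parameter_count` and
#'   `mac_count`.
#' @export
complexity <- function(config) {
  model <- if (inherits(config, "guided_unet")) config
           else build_model(config)
  cfg <- model$config
  n_par <- sum(vapply(model$params, function(p) length(p$value), 0))
  w <- cfg$base_width
  cs <- w * c(1L, 2L, 4L, 8L)
  hs <- cfg$input_size[1] %/% c(2L, 4L, 8L, 16L)
  ws <- cfg$input_size[2] %/% c(2L, 4L, 8L, 16L)
  conv_mac <- function(k, cin, cout, h, w2) as.numeric(k)^2 * cin * cout * h * w2
  mac <- 0
  cin <- cfg$in_channels
  for (s in 1:4) {
    mac <- mac + conv_mac(3, cin, cs[s], hs[s], ws[s]) +
      2 * 2 * conv_mac(3, cs[s], cs[s], hs[s], ws[s])
    cin <- cs[s]
  }
  if (cfg$use_pem) {
    n3 <- hs[3] * ws[3]; c3 <- cs[3]
    dsa_mac <- 3 * conv_mac(3, c3, c3, hs[3], ws[3]) +  # q/k/v convs
      2 * as.numeric(n3)^2 * c3 +                       # B = MN' and B.T
      conv_mac(1, c3, c3, hs[3], ws[3])                 # output projection
    mac <- mac + conv_mac(3, c3, c3, hs[3], ws[3]) +    # branch A
      2 * dsa_mac +                                     # dilation 2 and 3
      2 * 2 * conv_mac(1, c3, c3, hs[3], ws[3])         # two gated convs
  }
  if (cfg$use_csa) {
    n4 <- as.numeric(hs[4] * ws[4]); c4 <- cs[4]
    mac <- mac + 4 * c4 * n4^2 + 2 * c4^2 * n4 +        # channel stage
      4 * n4 * c4^2 + 2 * n4^2 * c4 + n4^2 * c4         # spatial stage + bias
  }
  if (cfg$use_sga) {
    n3 <- as.numeric(hs[3] * ws[3]); e <- cs[3]
    mac <- mac + 3 * conv_mac(1, e, e, hs[3], ws[3]) +  # q/k/v projections
      2 * e^2 +                                         # channel selection
      2 * n3^2 * e +                                    # QK' and A.V
      conv_mac(1, 2 * e, 2 * e, hs[3], ws[3])           # post projection
  } else {
    # plain concatenation has no multiplies
  }
  dec_in <- c(cs[4], 2L * cs[3], 2L * cs[2], 2L * cs[1])
  dec_mid <- c(cs[4], cs[3], cs[2], cs[1])
  dec_out <- c(cs[3], cs[2], cs[1], cs[1])
  dh <- c(hs[4], hs[3], hs[2], hs[1])
  dw <- c(ws[4], ws[3], ws[2], ws[1])
  for (s in 1:4) {
    mac <- mac + conv_mac(3, dec_in[s], dec_mid[s], dh[s], dw[s]) +
      conv_mac(3, dec_mid[s], dec_mid[s], dh[s], dw[s]) +
      conv_mac(1, dec_mid[s], dec_out[s], 2 * dh[s], 2 * dw[s])
  }
  mac <- mac + conv_mac(1, cs[1], 1, cfg$input_size[1], cfg$input_size[2])
  structure(list(parameter_count = n_par, mac_count = mac),
            class = "gu_complexity")
}

#' @export
print.gu_complexity <- function(x, ...) {
  cat(sprintf("parameters: %s   multiply-accumulates: %s\n",
              format(x$parameter_count, big.mark = ","),
              format(x$mac_count, big.mark = ",")))
  invisible(x)
}

#' @export
print.guided_unet <- function(x, ...) {
  cfg <- x$config
  on <- c("PEM", "CSA", "SGA")[c(cfg$use_pem, cfg$use_csa, cfg$use_sga)]
  cat(sprintf(
    "<guided_unet: %dx%d input, base width %d, %d heads, modules: %s>\n",
    cfg$input_size[1], cfg$input_size[2], cfg$base_width, cfg$n_heads,
    if (length(on)) paste(on, collapse = "+") else "none"))
  cat(sprintf("  %s trainable parameters in %d tensors\n",
              format(sum(vapply(x$params, function(p) length(p$value), 0)),
                     big.mark = ","),
              length(x$params)))
  invisible(x)
}

#' @export
summary.guided_unet <- function(object, ...) {
  print(object)
  print(complexity(object))
  invisible(object)
}
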