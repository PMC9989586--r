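# Reverse-mode automatic differentiation tape.
#
# Every forward operation returns a `gu_node`: an environment holding the
# computed value, its parent nodes, and a closure mapping the incoming
# gradient to per-parent gradients. `gu_backward()` topologically sorts the
# tape and accumulates gradients into trainable parameters (`gu_param`).
#
# Array convention throughout the package: feature maps are H x W x C x N
# (column-major, as delivered by png::readPNG); token matrices are
# n_tokens x dim with row-major spatial flattening, token = (row-1)*W + col.

.gu <- new.env(parent = emptyenv())
.gu$epoch <- 0L
.gu$interp_cache <- new.env(parent = emptyenv())

#' Create a trainable parameter
#'
#' Parameters are environments so gradients and optimiser state can be
#' accumulated in place during backpropagation.
#'
#' @param value Initial numeric array/matrix/vector.
#' @param decay Logical; whether weight decay applies (convolution/linear
#'   weights yes, biases and normalisation parameters no).
#' @param name Optional label used in summaries.
#' @return An object of class `gu_param`.
#' @keywords internal
gu_param <- function(value, decay = TRUE, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p$vel <- value * 0
  p$decay <- decay
  p$name <- name
  class(p) <- "gu_param"
  p
}

gu_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  n$param <- NULL
  n$seen <- 0L
  class(n) <- "gu_node"
  n
}

n_const <- function(x) gu_node(x)

n_leaf <- function(param) {
  n <- gu_node(param$value)
  n$param <- param
  n
}

#' @keywords internal
gu_zero_grads <- function(params) {
  for (p in params) {
    p$grad <- p$value * 0
  }
  invisible(NULL)
}

# Iterative post-order topological sort followed by reverse accumulation.
gu_backward <- function(root, seed = 1) {
  .gu$epoch <- .gu$epoch + 1L
  ep <- .gu$epoch
  order <- vector("list", 256L)
  cnt <- 0L
  stack <- vector("list", 64L)
  idx <- integer(64L)
  top <- 1L
  stack[[1L]] <- root
  idx[1L] <- 0L
  root$seen <- ep
  while (top > 0L) {
    node <- stack[[top]]
    i <- idx[top] + 1L
    if (i <= length(node$parents)) {
      idx[top] <- i
      p <- node$parents[[i]]
      if (p$seen != ep) {
        p$seen <- ep
        top <- top + 1L
        if (top > length(stack)) {
          length(stack) <- 2L * top
          idx <- c(idx, integer(top))
        }
        stack[[top]] <- p
        idx[top] <- 0L
      }
    } else {
      cnt <- cnt + 1L
      if (cnt > length(order)) length(order) <- 2L * cnt
      order[[cnt]] <- node
      top <- top - 1L
    }
  }
  root$grad <- seed
  for (k in seq(cnt, 1L)) {
    node <- order[[k]]
    g <- node$grad
    if (is.null(g)) next
    if (!is.null(node$param)) {
      node$param$grad <- node$param$grad + g
      next
    }
    if (is.null(node$backward)) next
    gs <- node$backward(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(root)
}

# ---- elementwise ----------------------------------------------------------

n_add <- function(a, b) {
  gu_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

n_mul <- function(a, b) {
  av <- a$value
  bv <- b$value
  gu_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

n_scale <- function(a, s) {
  gu_node(a$value * s, list(a), function(g) list(g * s))
}

n_relu <- function(a) {
  m <- a$value > 0
  gu_node(a$value * m, list(a), function(g) list(g * m))
}

n_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  gu_node(s, list(a), function(g) list(g * s * (1 - s)))
}

# ---- convolution ----------------------------------------------------------

n_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  has_b <- !is.null(b)
  y <- conv2d_fwd_cpp(x$value, w$value,
                      if (has_b) b$value else numeric(0),
                      as.integer(stride), as.integer(pad), as.integer(dil))
  parents <- if (has_b) list(x, w, b) else list(x, w)
  dy <- dim(y)
  xv <- x$value
  wv <- w$value
  gu_node(y, parents, function(g) {
    dim(g) <- dy
    r <- conv2d_bwd_cpp(xv, wv, g, as.integer(stride), as.integer(pad),
                        as.integer(dil), has_b)
    if (has_b) list(r$gx, r$gw, r$gb) else list(r$gx, r$gw)
  })
}

# ---- batch normalisation --------------------------------------------------

# state: environment with running_mean/running_var (per channel).
n_bn <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  xv <- x$value
  d <- dim(xv)
  C <- d[3]
  xm <- matrix(aperm(xv, c(1, 2, 4, 3)), ncol = C)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va <- pmax(va, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(invstd, each = m)
  ym <- xhat * rep(gamma$value, each = m) + rep(beta$value, each = m)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  gval <- gamma$value
  gu_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(array(g, d), c(1, 2, 4, 3)), ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (training) {
      dxhat <- gm * rep(gval, each = m)
      t1 <- colMeans(dxhat)
      t2 <- colMeans(dxhat * xhat)
      dxm <- (dxhat - rep(t1, each = m) - xhat * rep(t2, each = m)) *
        rep(invstd, each = m)
    } else {
      dxm <- gm * rep(gval * invstd, each = m)
    }
    dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

# ---- interpolation --------------------------------------------------------

# Dense bilinear interpolation matrix mapping n_in samples to n_out, using
# the half-pixel-centre convention. Linear in the input, so the adjoint is
# just the transpose.
interp_matrix <- function(n_out, n_in) {
  key <- paste0(n_out, "x", n_in)
  cached <- .gu$interp_cache[[key]]
  if (!is.null(cached)) return(cached)
  U <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    i0 <- floor(src)
    f <- src - i0
    lo <- min(max(i0, 0), n_in - 1)
    hi <- min(max(i0 + 1, 0), n_in - 1)
    U[i, lo + 1] <- U[i, lo + 1] + (1 - f)
    U[i, hi + 1] <- U[i, hi + 1] + f
  }
  .gu$interp_cache[[key]] <- U
  U
}

# Apply row interpolation matrix Uh and column matrix Uw to every channel
# and sample of a 4D array: y[,,c,n] = Uh %*% x[,,c,n] %*% t(Uw).
interp_apply <- function(x, Uh, Uw) {
  d <- dim(x)
  a <- Uh %*% matrix(x, d[1])
  a <- aperm(array(a, c(nrow(Uh), d[2], d[3], d[4])), c(2, 1, 3, 4))
  b <- Uw %*% matrix(a, d[2])
  aperm(array(b, c(nrow(Uw), nrow(Uh), d[3], d[4])), c(2, 1, 3, 4))
}

n_interp <- function(x, h_out, w_out) {
  d <- dim(x$value)
  Uh <- interp_matrix(h_out, d[1])
  Uw <- interp_matrix(w_out, d[2])
  y <- interp_apply(x$value, Uh, Uw)
  gu_node(y, list(x), function(g) {
    dim(g) <- c(h_out, w_out, d[3], d[4])
    list(interp_apply(g, t(Uh), t(Uw)))
  })
}

n_upsample2 <- function(x) {
  d <- dim(x$value)
  n_interp(x, 2L * d[1], 2L * d[2])
}

# ---- shape ops ------------------------------------------------------------

n_concat_c <- function(a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  ca <- da[3]
  cb <- db[3]
  y <- array(0, c(da[1], da[2], ca + cb, da[4]))
  y[, , seq_len(ca), ] <- a$value
  y[, , ca + seq_len(cb), ] <- b$value
  gu_node(y, list(a, b), function(g) {
    dim(g) <- dim(y)
    list(array(g[, , seq_len(ca), , drop = FALSE], da),
         array(g[, , ca + seq_len(cb), , drop = FALSE], db))
  })
}

# Extract sample n as a row-major token matrix (H*W) x C.
n_tokens <- function(x, n) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  xs <- array(x$value[, , , n], c(H, W, C))
  tok <- matrix(aperm(xs, c(2, 1, 3)), H * W, C)
  gu_node(tok, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , n] <- aperm(array(g, c(W, H, C)), c(2, 1, 3))
    list(gx)
  })
}

# Inverse of n_tokens for one sample: (H*W) x C tokens -> H x W x C array.
n_from_tokens <- function(tok, H, W) {
  C <- ncol(tok$value)
  y <- aperm(array(tok$value, c(W, H, C)), c(2, 1, 3))
  gu_node(y, list(tok), function(g) {
    dim(g) <- c(H, W, C)
    list(matrix(aperm(g, c(2, 1, 3)), H * W, C))
  })
}

n_stack <- function(nodes) {
  d <- dim(nodes[[1]]$value)
  N <- length(nodes)
  y <- array(0, c(d, N))
  for (i in seq_len(N)) y[, , , i] <- nodes[[i]]$value
  gu_node(y, nodes, function(g) {
    dim(g) <- c(d, N)
    lapply(seq_len(N), function(i) array(g[, , , i], d))
  })
}

n_cols <- function(a, idx) {
  av <- a$value
  gu_node(av[, idx, drop = FALSE], list(a), function(g) {
    ga <- av * 0
    ga[, idx] <- g
    list(ga)
  })
}

n_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  y <- do.call(cbind, lapply(nodes, function(n) n$value))
  gu_node(y, nodes, function(g) {
    off <- c(0L, cumsum(widths))
    lapply(seq_along(nodes), function(i) {
      g[, (off[i] + 1):off[i + 1], drop = FALSE]
    })
  })
}

# ---- matrix ops -----------------------------------------------------------

n_matmul <- function(a, b) {
  av <- a$value
  bv <- b$value
  gu_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

n_transpose <- function(a) {
  gu_node(t(a$value), list(a), function(g) list(t(g)))
}

n_softmax_rows <- function(a) {
  av <- a$value
  mx <- apply(av, 1, max)
  s <- exp(av - mx)
  s <- s / rowSums(s)
  gu_node(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

n_softmax_cols <- function(a) {
  av <- a$value
  mx <- apply(av, 2, max)
  s <- exp(sweep(av, 2, mx))
  s <- sweep(s, 2, colSums(s), "/")
  gu_node(s, list(a), function(g) {
    list(s * sweep(g, 2, colSums(g * s)))
  })
}

n_colmeans <- function(a) {
  m <- nrow(a$value)
  gu_node(colMeans(a$value), list(a), function(g) {
    list(matrix(rep(g / m, each = m), m))
  })
}

n_matvec <- function(w, p) {
  wv <- w$value
  pv <- p$value
  gu_node(as.vector(wv %*% pv), list(w, p), function(g) {
    list(outer(g, pv), as.vector(t(wv) %*% g))
  })
}

# Scale column (channel) j of a token matrix by a[j].
n_scale_cols <- function(tok, a) {
  tv <- tok$value
  av <- a$value
  m <- nrow(tv)
  gu_node(tv * rep(av, each = m), list(tok, a), function(g) {
    list(g * rep(av, each = m), colSums(g * tv))
  })
}

# Value-dependent position bias (learned absolute position embedding):
# p[i,j] = sum_d v[i,d] * A[i,j,d] with A a trainable n x n x d table.
n_posbias <- function(vtok, atab) {
  vv <- vtok$value
  av <- atab$value
  n <- nrow(vv)
  d <- ncol(vv)
  p <- matrix(0, n, n)
  for (k in seq_len(d)) p <- p + av[, , k] * vv[, k]
  gu_node(p, list(vtok, atab), function(g) {
    dv <- matrix(0, n, d)
    da <- array(0, dim(av))
    for (k in seq_len(d)) {
      dv[, k] <- rowSums(g * av[, , k])
      da[, , k] <- g * vv[, k]
    }
    list(dv, da)
  })
}
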