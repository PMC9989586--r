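# Independent brute-force references: explicit loops, no shared code with
# the package internals they check.

# Direct convolution by sextuple loop; x: H x W x C, w: kh x kw x Cin x Cout.
conv_oracle <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (!is.null(b)) b[co] else 0
    for (ci in 1:C) for (i in 1:kh) for (j in 1:kw) {
      ih <- (ho - 1) * stride - pad + (i - 1) * dil + 1
      iw <- (wo - 1) * stride - pad + (j - 1) * dil + 1
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        acc <- acc + x[ih, iw, ci] * w[i, j, ci, co]
    }
    y[ho, wo, co] <- acc
  }
  y
}

# Row-major token flattening by loop: token (r-1)*W + c.
tokens_oracle <- function(f) {
  d <- dim(f)
  tok <- matrix(0, d[1] * d[2], d[3])
  for (r in 1:d[1]) for (c in 1:d[2])
    tok[(r - 1) * d[2] + c, ] <- f[r, c, ]
  tok
}

untokens_oracle <- function(tok, H, W) {
  C <- ncol(tok)
  f <- array(0, c(H, W, C))
  for (r in 1:H) for (c in 1:W) f[r, c, ] <- tok[(r - 1) * W + c, ]
  f
}

softmax_vec_oracle <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Multi-head attention by explicit exp/normalise/weighted-sum loops.
# bias: NULL, an nq x nk matrix, or nq x nk x n_heads array.
attention_oracle <- function(q, k, v, bias = NULL, n_heads = 1,
                             scale = NULL, axis = "key") {
  d <- ncol(q)
  dh <- d %/% n_heads
  if (is.null(scale)) scale <- 1 / sqrt(dh)
  nq <- nrow(q); nk <- nrow(k)
  out <- matrix(0, nq, d)
  for (h in 1:n_heads) {
    idx <- (h - 1) * dh + 1:dh
    e <- matrix(0, nq, nk)
    for (i in 1:nq) for (j in 1:nk) {
      e[i, j] <- scale * sum(q[i, idx] * k[j, idx])
      if (!is.null(bias))
        e[i, j] <- e[i, j] +
          (if (length(dim(bias)) == 3) bias[i, j, h] else bias[i, j])
    }
    a <- matrix(0, nq, nk)
    if (axis == "key") {
      for (i in 1:nq) a[i, ] <- softmax_vec_oracle(e[i, ])
    } else {
      for (j in 1:nk) a[, j] <- softmax_vec_oracle(e[, j])
    }
    for (i in 1:nq) for (dd in idx) out[i, dd] <- sum(a[i, ] * v[, dd])
  }
  out
}

# Dilated self-attention by loops, reusing the block's frozen weights.
dsa_oracle <- function(x, block) {
  dl <- block$dilation
  M <- tokens_oracle(conv_oracle(x, block$q$w$value, pad = dl, dil = dl))
  N <- tokens_oracle(conv_oracle(x, block$k$w$value, pad = dl, dil = dl))
  T <- tokens_oracle(conv_oracle(x, block$v$w$value, pad = dl, dil = dl))
  sc <- if (isTRUE(block$scale)) 1 / sqrt(ncol(M) / block$n_heads) else 1
  out <- attention_oracle(M, N, T, n_heads = block$n_heads, scale = sc,
                          axis = block$axis)
  y <- untokens_oracle(out, dim(x)[1], dim(x)[2])
  if (!is.null(block$proj))
    y <- conv_oracle(y, block$proj$w$value, block$proj$b$value)
  if (isTRUE(block$residual)) y <- y + x
  y
}

# Gated convolution per-pixel: sigmoid(gate) * relu(embedding).
gated_conv_oracle <- function(f_high, f_low, params) {
  d <- dim(f_low)
  cout <- dim(params$w_f)[4]
  y <- array(0, c(d[1], d[2], cout))
  for (r in 1:d[1]) for (c in 1:d[2]) for (co in 1:cout) {
    gate <- params$b_g[co] + sum(f_high[r, c, ] * params$w_g[1, 1, , co])
    emb <- params$b_f[co] + sum(f_low[r, c, ] * params$w_f[1, 1, , co])
    y[r, c, co] <- max(emb, 0) / (1 + exp(-gate))
  }
  y
}

# Channel-token self-attention stage by loops, frozen block weights.
channel_stage_oracle <- function(x, block) {
  tok <- tokens_oracle(x)
  ct <- t(tok)
  st <- block$ch
  q <- ct %*% st$q$w$value
  k <- ct %*% st$k$w$value
  v <- ct %*% st$v$w$value
  dh <- block$n_tokens %/% block$n_heads
  out <- attention_oracle(q, k, v, n_heads = block$n_heads,
                          scale = 1 / sqrt(dh))
  res <- t(out %*% st$o$w$value)
  if (isTRUE(block$residual)) res <- tok + res
  untokens_oracle(res, dim(x)[1], dim(x)[2])
}

# Spatial-token self-attention with the learned position bias, by loops.
spatial_stage_oracle <- function(x, block) {
  tok <- tokens_oracle(x)
  st <- block$sp
  q <- tok %*% st$q$w$value
  k <- tok %*% st$k$w$value
  v <- tok %*% st$v$w$value
  A <- st$bias$value
  n <- nrow(tok)
  dh <- block$channels %/% block$n_heads
  out <- matrix(0, n, block$channels)
  for (h in 1:block$n_heads) {
    idx <- (h - 1) * dh + 1:dh
    e <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      e[i, j] <- sum(q[i, idx] * k[j, idx]) / sqrt(dh) +
        sum(v[i, idx] * A[i, j, ])
    }
    a <- matrix(0, n, n)
    for (i in 1:n) a[i, ] <- softmax_vec_oracle(e[i, ])
    for (i in 1:n) for (dd in idx) out[i, dd] <- sum(a[i, ] * v[, dd])
  }
  res <- out %*% st$o$w$value
  if (isTRUE(block$residual)) res <- tok + res
  untokens_oracle(res, dim(x)[1], dim(x)[2])
}

# Channel selection by loops.
channel_selection_oracle <- function(f, w) {
  d <- dim(f)
  p <- numeric(d[3])
  for (c in 1:d[3]) p[c] <- sum(f[, , c]) / (d[1] * d[2])
  a <- numeric(d[3])
  for (c in 1:d[3]) a[c] <- 1 / (1 + exp(-sum(w[c, ] * p)))
  out <- f
  for (c in 1:d[3]) out[, , c] <- f[, , c] * a[c]
  list(output = out, weights = a)
}

# SGA by loops: 1x1 projections, CS on K and Q, per-head cross-attention,
# context concatenated with high, post 1x1 projection.
sga_oracle <- function(low, high, block) {
  proj <- function(f, cv) conv_oracle(f, cv$w$value, cv$b$value)
  ktok <- tokens_oracle(proj(low, block$pk))
  vtok <- tokens_oracle(proj(low, block$pv))
  qtok <- tokens_oracle(proj(high, block$pq))
  H <- dim(low)[1]; W <- dim(low)[2]
  cs <- function(tok, wmat) {
    p <- colSums(tok) / nrow(tok)
    a <- 1 / (1 + exp(-as.vector(wmat %*% p)))
    sweep(tok, 2, a, "*")
  }
  ktok <- cs(ktok, block$cs_k$value)
  qtok <- cs(qtok, block$cs_q$value)
  dh <- block$embed %/% block$n_heads
  ctx <- attention_oracle(qtok, ktok, vtok, n_heads = block$n_heads,
                          scale = 1 / sqrt(dh))
  ctxf <- untokens_oracle(ctx, H, W)
  cat3 <- array(0, c(H, W, block$embed + dim(high)[3]))
  cat3[, , 1:block$embed] <- ctxf
  cat3[, , block$embed + seq_len(dim(high)[3])] <- high
  list(context = ctxf,
       output = conv_oracle(cat3, block$post$w$value, block$post$b$value))
}

rand_feat <- function(H, W, C, sd = 1) array(rnorm(H * W * C, sd = sd), c(H, W, C))

expect_close <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
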