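# Shared attention primitives: scaled dot-product MHSA and the dilated
# self-attention convolution.

test_that("single-token and symmetric cases give the exact closed forms", {
  # one token: softmax of a single logit is 1, output is v
  q <- matrix(rnorm(4), 1)
  v <- matrix(rnorm(4), 1)
  res <- scaled_dot_attention(q, q, v)
  expect_equal(as.numeric(res$attention), 1)
  expect_equal(res$output, v)

  # two identical key tokens: every query splits 50/50
  k <- matrix(rep(rnorm(4), each = 2), 2, 4)
  v2 <- matrix(rnorm(8), 2, 4)
  res <- scaled_dot_attention(matrix(rnorm(4), 1), k, v2)
  expect_equal(as.vector(res$attention[1, , 1]), c(0.5, 0.5))
})

test_that("scaled_dot_attention matches the explicit-loop reference", {
  set.seed(11)
  q <- matrix(rnorm(24), 6, 4)
  k <- matrix(rnorm(24), 6, 4)
  v <- matrix(rnorm(24), 6, 4)
  res <- scaled_dot_attention(q, k, v, n_heads = 1)
  expect_close(res$output, attention_oracle(q, k, v, n_heads = 1), 1e-5)

  # multiple heads, cross-attention shapes, and an additive bias
  q2 <- matrix(rnorm(5 * 8), 5, 8)
  k2 <- matrix(rnorm(7 * 8), 7, 8)
  v2 <- matrix(rnorm(7 * 8), 7, 8)
  b <- matrix(rnorm(35), 5, 7)
  res2 <- scaled_dot_attention(q2, k2, v2, bias = b, n_heads = 2)
  expect_close(res2$output,
               attention_oracle(q2, k2, v2, bias = b, n_heads = 2), 1e-5)
})

test_that("attention rows are probability vectors and keys can be permuted", {
  set.seed(12)
  for (rep in 1:20) {
    nq <- sample(1:9, 1); nk <- sample(1:9, 1)
    nh <- sample(c(1, 2, 4), 1); d <- nh * sample(1:4, 1)
    q <- matrix(rnorm(nq * d), nq)
    k <- matrix(rnorm(nk * d), nk)
    v <- matrix(rnorm(nk * d), nk)
    res <- scaled_dot_attention(q, k, v, n_heads = nh)
    for (h in seq_len(nh))
      expect_close(rowSums(res$attention[, , h, drop = FALSE][, , 1, drop = FALSE]),
                   rep(1, nq), 1e-6)
    expect_true(all(res$attention >= 0 & res$attention <= 1))
    # permutation equivariance: permuting key/value pairs leaves outputs alone
    perm <- sample(nk)
    res_p <- scaled_dot_attention(q, k[perm, , drop = FALSE],
                                  v[perm, , drop = FALSE], n_heads = nh)
    expect_close(res$output, res_p$output, 1e-10)
  }
})

test_that("head count must divide the embedding dimension", {
  q <- matrix(rnorm(12), 3, 4)
  expect_error(scaled_dot_attention(q, q, q, n_heads = 3), "divide")
  expect_error(scaled_dot_attention(q, matrix(rnorm(6), 2, 3), q), "dimension")
})

test_that("dsa_forward preserves shape for dilations 1-3 and normalises B", {
  set.seed(13)
  x <- rand_feat(8, 8, 4)
  for (dl in 1:3) {
    y <- dsa_forward(x, dilation = dl)
    expect_identical(dim(y), dim(x))
  }
  expect_error(dsa_block(4, dilation = 0), "positive")

  # the attention map hidden inside DSA is softmax-normalised: probe it
  # through the node machinery with a record environment
  blk <- dsa_block(4, 2)
  qf <- conv_oracle(x, blk$q$w$value, pad = 2, dil = 2)
  kf <- conv_oracle(x, blk$k$w$value, pad = 2, dil = 2)
  M <- tokens_oracle(qf); N <- tokens_oracle(kf)
  B <- t(apply(M %*% t(N), 1, softmax_vec_oracle))
  expect_close(rowSums(B), rep(1, 64), 1e-6)
})

test_that("dsa_forward matches the loop oracle with frozen weights", {
  set.seed(14)
  x <- rand_feat(4, 4, 2)
  for (axis in c("key", "query")) {
    blk <- dsa_block(2, dilation = 2, axis = axis)
    expect_close(dsa_forward(x, block = blk), dsa_oracle(x, blk), 1e-5)
  }
  # residual + scale variants, and a multi-head split
  blk2 <- dsa_block(4, dilation = 3, n_heads = 2, scale = TRUE,
                    residual = TRUE)
  x2 <- rand_feat(5, 5, 4)
  expect_close(dsa_forward(x2, block = blk2), dsa_oracle(x2, blk2), 1e-5)
})

test_that("token flattening is row-major and round-trips", {
  x <- rand_feat(3, 5, 2)
  tok <- guidedunet:::n_tokens(guidedunet:::n_const(guidedunet:::as_batch(x)), 1)
  expect_equal(tok$value, tokens_oracle(x))
  back <- guidedunet:::n_from_tokens(tok, 3, 5)
  expect_equal(back$value, x)
})
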