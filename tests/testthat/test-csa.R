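# Channel-spatial attention at the bottleneck.

test_that("channel attention of a channel-uniform feature is row-uniform", {
  set.seed(31)
  plane <- matrix(rnorm(16), 4, 4)
  x <- array(rep(plane, 4), c(4, 4, 4))  # all channels identical
  res <- channel_mhsa(x, n_heads = 2, return_attention = TRUE)
  a <- res$attention$channel_attention
  for (h in seq_len(dim(a)[3]))
    expect_close(a[, , h], matrix(1 / 4, 4, 4), 1e-9)
})

test_that("channel and spatial stages match their loop oracles", {
  set.seed(32)
  x <- rand_feat(4, 4, 4)
  blk <- csa_block(4, 16, n_heads = 4)
  expect_close(channel_mhsa(x, block = blk), channel_stage_oracle(x, blk), 1e-5)
  expect_close(spatial_mhsa(x, block = blk), spatial_stage_oracle(x, blk), 1e-5)
  # no-residual variant on an odd token count (single head)
  blk2 <- csa_block(4, 9, n_heads = 1, residual = FALSE)
  x2 <- rand_feat(3, 3, 4)
  expect_close(channel_mhsa(x2, block = blk2), channel_stage_oracle(x2, blk2), 1e-5)
  expect_close(spatial_mhsa(x2, block = blk2), spatial_stage_oracle(x2, blk2), 1e-5)
})

test_that("zero position bias reduces the spatial stage to plain attention", {
  set.seed(33)
  x <- rand_feat(4, 4, 4)
  blk <- csa_block(4, 16, n_heads = 2, residual = FALSE)
  blk$sp$bias$value[] <- 0
  tok <- tokens_oracle(x)
  plain <- scaled_dot_attention(tok %*% blk$sp$q$w$value,
                                tok %*% blk$sp$k$w$value,
                                tok %*% blk$sp$v$w$value,
                                n_heads = 2)$output %*% blk$sp$o$w$value
  expect_close(spatial_mhsa(x, block = blk), untokens_oracle(plain, 4, 4), 1e-6)
})

test_that("a single spatial token passes straight through the value path", {
  set.seed(34)
  x <- array(rnorm(8), c(1, 1, 8))
  blk <- csa_block(8, 1, n_heads = 1, residual = FALSE)
  expected <- matrix(x, 1, 8) %*% blk$sp$v$w$value %*% blk$sp$o$w$value
  expect_close(spatial_mhsa(x, block = blk), array(expected, c(1, 1, 8)), 1e-8)
})

test_that("csa_forward is channel-then-spatial, shape-preserving, gated by `enabled`", {
  set.seed(35)
  x <- rand_feat(10, 10, 16)
  blk <- csa_block(16, 100, n_heads = 4)
  expect_identical(dim(csa_forward(x, block = blk)), dim(x))
  expect_identical(csa_forward(x, enabled = FALSE), x)
  # freeze the channel stage to the identity (residual on, output
  # projection zeroed): the series equals the spatial stage alone
  x2 <- rand_feat(4, 4, 4)
  blk2 <- csa_block(4, 16, n_heads = 2)
  blk2$ch$o$w$value[] <- 0
  expect_close(csa_forward(x2, block = blk2),
               spatial_mhsa(x2, block = blk2), 1e-6)
})

test_that("token views of the feature map round-trip losslessly", {
  x <- rand_feat(5, 7, 3)
  tok <- tokens_oracle(x)
  expect_equal(untokens_oracle(tok, 5, 7), x)
  ct <- t(tok)  # channel-token view
  expect_equal(untokens_oracle(t(ct), 5, 7), x)
})
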