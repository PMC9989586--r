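# Network assembly: geometry, ablation switches, complexity accounting,
# feature dumps, forward determinism.

tiny_cfg <- function(...) {
  model_config(base_width = 8L, input_size = c(64L, 64L), seed = 3L, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(input_size = c(100, 100)), "divisible by 16")
  expect_error(model_config(base_width = 0), "base_width")
  expect_error(model_config(input_size = c(48, 48), n_heads = 7), "heads")
})

test_that("a tiny model builds, runs forward, and respects the output contract", {
  m <- build_model(tiny_cfg())
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- predict(m, x)
  expect_identical(dim(p), c(64L, 64L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(m, array(0, c(32, 32, 3))), "resize")
})

test_that("encoder halves the spatial size at every stage", {
  m <- build_model(tiny_cfg())
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fm <- dump_feature_maps(m, x, c("enc1", "enc2", "enc3", "enc4"))
  for (s in 1:4)
    expect_identical(dim(fm[[paste0("enc", s)]])[1:2],
                     as.integer(c(64, 64) / 2^s))
})

test_that("decoder snapshots double in size; PEM and SGA contracts visible", {
  m <- build_model(tiny_cfg())
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fm <- dump_feature_maps(m, x, c("dec1", "dec2", "dec3", "dec4",
                                  "pem_in", "pem_out", "sga_concat"))
  for (s in 1:4)
    expect_identical(dim(fm[[paste0("dec", s)]])[1:2],
                     as.integer(c(64, 64) / 2^(4 - s)))
  expect_identical(dim(fm$pem_in), dim(fm$pem_out))
  # pre-projection SGA concatenation carries C_low + C_high channels
  expect_identical(dim(fm$sga_concat)[3], dim(fm$pem_out)[3] + dim(fm$dec1)[3])
  expect_error(dump_feature_maps(m, x, "nonsense"), "unknown stage")
})

test_that("identical inputs in one batch give identical outputs, forward is deterministic", {
  m <- build_model(tiny_cfg())
  x1 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  batch <- array(c(x1, x1), c(64, 64, 3, 2))
  p <- predict(m, batch)
  expect_identical(p[, , 1], p[, , 2])
  expect_identical(predict(m, x1), predict(m, x1))
})

test_that("disabling modules changes topology the way the switches promise", {
  base <- build_model(tiny_cfg(use_pem = FALSE, use_csa = FALSE,
                               use_sga = FALSE))
  expect_null(base$pem); expect_null(base$csa); expect_null(base$sga)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fm <- dump_feature_maps(base, x, c("sga_concat", "prob"))
  expect_identical(dim(fm$sga_concat)[3], 64L)  # plain concat: 32 + 32
  expect_error(dump_feature_maps(base, x, "pem_out"), "disabled")
})

test_that("parameter and MAC counts are monotone over the ablation lattice", {
  switches <- expand.grid(pem = c(FALSE, TRUE), csa = c(FALSE, TRUE),
                          sga = c(FALSE, TRUE))
  reports <- lapply(seq_len(nrow(switches)), function(i)
    complexity(tiny_cfg(use_pem = switches$pem[i], use_csa = switches$csa[i],
                        use_sga = switches$sga[i])))
  for (i in seq_len(nrow(switches))) for (j in seq_len(nrow(switches))) {
    if (i == j) next
    dominates <- all(unlist(switches[j, ]) >= unlist(switches[i, ])) &&
      any(unlist(switches[j, ]) > unlist(switches[i, ]))
    if (dominates) {
      expect_gt(reports[[j]]$parameter_count, reports[[i]]$parameter_count)
      expect_gt(reports[[j]]$mac_count, reports[[i]]$mac_count)
    }
  }
})

test_that("complexity parameter counts equal the built model exactly; conv MACs are closed-form", {
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  rep1 <- complexity(cfg)
  expect_equal(rep1$parameter_count,
               sum(vapply(m$params, function(p) length(p$value), 0)))
  # one convolution layer: k^2 * C_in * C_out * H_out * W_out
  k <- 3; cin <- 5; cout <- 7; H <- 10; W <- 12
  expect_equal(k^2 * cin * cout * H * W, 37800)
  x <- array(runif(H * W * cin), c(H, W, cin, 1))
  w <- array(runif(k * k * cin * cout), c(k, k, cin, cout))
  y <- guidedunet:::conv2d_fwd_cpp(x, w, numeric(0), 1L, 1L, 1L)
  expect_identical(dim(y)[1:3], c(10L, 12L, 7L))
})

test_that("compiled convolution matches the loop oracle including stride/dilation", {
  set.seed(71)
  x <- rand_feat(7, 7, 3)
  w <- array(rnorm(3 * 3 * 3 * 4, sd = 0.5), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (cfg in list(c(1, 1, 1), c(2, 1, 1), c(1, 2, 2), c(1, 3, 3))) {
    y <- guidedunet:::conv2d_fwd_cpp(guidedunet:::as_batch(x), w, b,
                                     cfg[1], cfg[2], cfg[3])
    orc <- conv_oracle(x, w, b, cfg[1], cfg[2], cfg[3])
    expect_close(array(y, dim(y)[1:3]), orc, 1e-10)
  }
})
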