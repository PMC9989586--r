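# Data pipeline: loading, resizing, augmentation, splitting, synthesis.

make_pair_dirs <- function(samples) {
  dir <- tempfile("pairs")
  write_dataset(samples, dir)
  dir
}

test_that("load_pairs reads matched PNG pairs sorted by id and binarises masks", {
  samples <- generate_synthetic(3, synthetic_params(seed = 61))
  dir <- make_pair_dirs(samples)
  got <- load_pairs(file.path(dir, "images"), file.path(dir, "masks"))
  expect_length(got, 3)
  ids <- vapply(got, `[[`, "", "id")
  expect_identical(ids, sort(ids))
  for (i in 1:3) {
    expect_true(all(got[[i]]$mask %in% c(0, 1)))
    expect_equal(got[[i]]$mask, samples[[i]]$mask)
    expect_close(got[[i]]$image, samples[[i]]$image, 1 / 255)
  }
  # a mask written as 0/255 binarises to 0/1
  m255 <- png::readPNG(file.path(dir, "masks", paste0(samples[[1]]$id, ".png")))
  expect_true(all(m255 %in% c(0, 1)))  # writePNG scaled 0/1 -> 0/255 -> read back
})

test_that("an image without a mask raises an error naming the stem", {
  samples <- generate_synthetic(2, synthetic_params(seed = 62))
  dir <- make_pair_dirs(samples)
  file.remove(file.path(dir, "masks", paste0(samples[[2]]$id, ".png")))
  expect_error(load_pairs(file.path(dir, "images"), file.path(dir, "masks")),
               samples[[2]]$id)
})

test_that("resizing is bilinear for images, nearest for masks, area-preserving", {
  set.seed(63)
  # 384 x 288 -> 320 x 320, like clinical colonoscopy frames
  img <- array(runif(384 * 288 * 3), c(384, 288, 3))
  rr <- matrix(seq_len(384), 384, 288)
  cc <- matrix(seq_len(288), 384, 288, byrow = TRUE)
  disk <- ((rr - 192)^2 + (cc - 144)^2 <= 100^2) * 1
  s <- seg_sample(img, disk, "frame")
  r <- resize_sample(s, c(320, 320))
  expect_identical(dim(r$image), c(320L, 320L, 3L))
  expect_true(all(r$mask %in% c(0, 1)))
  # identity resize leaves the mask untouched
  expect_identical(resize_sample(s, c(384, 288))$mask, s$mask)
  # area fraction of a large centred disk is preserved within 5%
  expect_lt(abs(mean(r$mask) - mean(s$mask)) / mean(s$mask), 0.05)
})

test_that("flips are involutions and preserve foreground counts exactly", {
  s <- generate_synthetic(1, synthetic_params(seed = 64))[[1]]
  expect_identical(flip_h(flip_h(s)), s)
  expect_identical(flip_v(flip_v(s)), s)
  n_fg <- sum(s$mask)
  expect_identical(sum(flip_h(s)$mask), n_fg)
  expect_identical(sum(flip_v(s)$mask), n_fg)
  expect_identical(sum(rot90_sample(s)$mask), n_fg)
  r4 <- rot90_sample(rot90_sample(rot90_sample(rot90_sample(s))))
  expect_identical(r4, s)
})

test_that("augmentation is seed-deterministic and keeps masks binary and aligned", {
  s <- generate_synthetic(1, synthetic_params(seed = 65))[[1]]
  a1 <- augment_sample(s, seed = 7)
  a2 <- augment_sample(s, seed = 7)
  expect_identical(a1, a2)
  a3 <- augment_sample(s, seed = 8)
  expect_false(identical(a1, a3))
  for (a in list(a1, a3)) {
    expect_identical(dim(a$image)[1:2], dim(a$mask))
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  # individual continuous transforms also preserve binarity
  expect_true(all(rotate_sample(s, 17)$mask %in% c(0, 1)))
  expect_true(all(crop_resize(s, 0.85, 0.3, 0.7)$mask %in% c(0, 1)))
  expect_true(all(grid_distort(s)$mask %in% c(0, 1)))
})

test_that("splits are exact, disjoint, exhaustive and reproducible", {
  samples <- as.list(1:1000)
  sp <- split_samples(samples, c(0.8, 0.1, 0.1), seed = 9)
  expect_identical(lengths(sp), c(train = 800L, val = 100L, test = 100L))
  all_ids <- sort(unlist(sp, use.names = FALSE))
  expect_identical(all_ids, 1:1000)
  sp2 <- split_samples(samples, c(0.8, 0.1, 0.1), seed = 9)
  expect_identical(sp, sp2)
  sp3 <- split_samples(samples, c(0.8, 0.1, 0.1), seed = 10)
  expect_false(identical(sp, sp3))
})

test_that("synthetic generation is reproducible with non-empty in-range masks", {
  prm <- synthetic_params(seed = 66)
  s1 <- generate_synthetic(5, prm)
  s2 <- generate_synthetic(5, prm)
  expect_identical(s1, s2)
  for (s in s1) {
    expect_gt(sum(s$mask), 0)
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$mask %in% c(0, 1)))
  }
})

test_that("a single undeformed-radius blob lands in the predicted area band", {
  prm <- synthetic_params(n_blobs = c(1, 1), radius = c(8, 8), seed = 67,
                          noise_sigma = 0)
  for (s in generate_synthetic(10, prm)) {
    area <- sum(s$mask)
    expect_gte(area, pi * 6^2)   # radius no smaller than r0*(1-deform)
    expect_lte(area, pi * 10^2)  # radius no larger than r0*(1+deform)
  }
})

test_that("mean foreground fraction of default blobs sits in the working band", {
  samples <- generate_synthetic(100, synthetic_params(seed = 68))
  frac <- mean(vapply(samples, function(s) mean(s$mask), 0))
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.32)
})
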