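# Geometric data augmentation. Exact transforms (flips, quarter-turns)
# are index permutations; continuous transforms (rotation, crop, grid
# distortion) go through an inverse-mapping warp sampling the image
# bilinearly and the mask by nearest neighbour, so image and mask always
# receive the identical geometric transform and the mask stays binary.

#' Exact flips and quarter-turn rotation
#'
#' Index-permutation transforms that preserve the foreground pixel count
#' exactly. Flips are involutions: applied twice they give back the input.
#'
#' @param sample A [seg_sample()].
#' @return The transformed sample.
#' @export
flip_h <- function(sample) {
  w <- dim(sample$image)[2]
  seg_sample(sample$image[, w:1, , drop = FALSE], sample$mask[, w:1],
             sample$id)
}

#' @rdname flip_h
#' @export
flip_v <- function(sample) {
  h <- dim(sample$image)[1]
  seg_sample(sample$image[h:1, , , drop = FALSE], sample$mask[h:1, ],
             sample$id)
}

#' @rdname flip_h
#' @export
rot90_sample <- function(sample) {
  img <- aperm(sample$image, c(2, 1, 3))
  h <- dim(img)[1]
  seg_sample(img[h:1, , , drop = FALSE], t(sample$mask)[h:1, ], sample$id)
}

# Inverse-mapping warp: src_r/src_c give, for every output pixel, the
# (real-valued, 1-based) source coordinates.
warp_sample <- function(sample, src_r, src_c) {
  d <- dim(sample$image)
  H <- d[1]; W <- d[2]
  r0 <- floor(src_r); fr <- src_r - r0
  c0 <- floor(src_c); fc <- src_c - c0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  i00 <- cbind(as.vector(cl(r0, H)), as.vector(cl(c0, W)))
  i10 <- cbind(as.vector(cl(r0 + 1, H)), as.vector(cl(c0, W)))
  i01 <- cbind(as.vector(cl(r0, H)), as.vector(cl(c0 + 1, W)))
  i11 <- cbind(as.vector(cl(r0 + 1, H)), as.vector(cl(c0 + 1, W)))
  w00 <- as.vector((1 - fr) * (1 - fc)); w10 <- as.vector(fr * (1 - fc))
  w01 <- as.vector((1 - fr) * fc); w11 <- as.vector(fr * fc)
  img <- array(0, d)
  for (ch in seq_len(d[3])) {
    plane <- sample$image[, , ch]
    img[, , ch] <- matrix(plane[i00] * w00 + plane[i10] * w10 +
                          plane[i01] * w01 + plane[i11] * w11, H, W)
  }
  rn <- cbind(as.vector(cl(round(src_r), H)), as.vector(cl(round(src_c), W)))
  inside <- as.vector(src_r >= 0.5 & src_r <= H + 0.5 &
                      src_c >= 0.5 & src_c <= W + 0.5)
  msk <- matrix(sample$mask[rn] * inside, H, W)
  seg_sample(pmin(pmax(img, 0), 1), msk, sample$id)
}

#' Rotate a sample by an arbitrary angle
#'
#' Rotation about the image centre; the image is sampled bilinearly, the
#' mask by nearest neighbour (pixels mapped from outside the canvas become
#' background).
#'
#' @param sample A [seg_sample()].
#' @param angle Angle in degrees (counter-clockwise).
#' @return The rotated sample.
#' @export
rotate_sample <- function(sample, angle) {
  d <- dim(sample$image)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  rr <- matrix(seq_len(H), H, W) - cr
  ccol <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  src_r <- cos(th) * rr - sin(th) * ccol + cr
  src_c <- sin(th) * rr + cos(th) * ccol + cc
  warp_sample(sample, src_r, src_c)
}

#' Random crop-and-resize
#'
#' Crops a window covering `scale` of each spatial extent at the given
#' offsets (fractions of the slack), then resizes back to the original
#' resolution so batch shapes stay constant.
#'
#' @param sample A [seg_sample()].
#' @param scale Linear crop scale in (0, 1].
#' @param off_r,off_c Offsets in \[0,1\] within the available slack.
#' @return The cropped-and-resized sample.
#' @export
crop_resize <- function(sample, scale, off_r = 0.5, off_c = 0.5) {
  d <- dim(sample$image)
  h <- max(2L, floor(d[1] * scale)); w <- max(2L, floor(d[2] * scale))
  r0 <- 1L + floor(off_r * (d[1] - h))
  c0 <- 1L + floor(off_c * (d[2] - w))
  cropped <- seg_sample(
    sample$image[r0:(r0 + h - 1L), c0:(c0 + w - 1L), , drop = FALSE],
    sample$mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)], sample$id)
  resize_sample(cropped, d[1:2])
}

#' Grid distortion
#'
#' Perturbs a `grid x grid` lattice of control points by up to
#' `magnitude` of one cell and warps with the bilinearly interpolated
#' displacement field.
#'
#' @param sample A [seg_sample()].
#' @param grid Number of cells per axis (default 5).
#' @param magnitude Maximum displacement as a fraction of one cell
#'   (default 0.1).
#' @param disp Optional precomputed `(grid+1) x (grid+1) x 2` node
#'   displacement array in cell units; drawn from the current RNG stream
#'   when `NULL`.
#' @return The distorted sample.
#' @export
grid_distort <- function(sample, grid = 5L, magnitude = 0.1, disp = NULL) {
  d <- dim(sample$image)
  H <- d[1]; W <- d[2]
  if (is.null(disp))
    disp <- array(stats::runif((grid + 1)^2 * 2, -magnitude, magnitude),
                  c(grid + 1, grid + 1, 2))
  # interpolate node displacements (in cell units) to a per-pixel field
  Ur <- interp_matrix(H, grid + 1L)
  Uc <- interp_matrix(W, grid + 1L)
  dr <- Ur %*% disp[, , 1] %*% t(Uc) * (H / grid)
  dc <- Ur %*% disp[, , 2] %*% t(Uc) * (W / grid)
  src_r <- matrix(seq_len(H), H, W) + dr
  src_c <- matrix(seq_len(W), H, W, byrow = TRUE) + dc
  warp_sample(sample, src_r, src_c)
}

#' Randomly augment a sample
#'
#' Applies, in order: random crop (scale 0.8-1.0, resized back), random
#' rotation (uniform in +/-30 degrees), horizontal and vertical flips
#' (each with probability 0.5), and grid distortion (5x5 grid, +/-10% of
#' one cell). All draws come from `seed`, so the same seed gives a
#' bitwise-identical result; the global RNG stream is left untouched.
#'
#' @param sample A [seg_sample()].
#' @param seed Integer seed.
#' @param crop,rotation,flips,distortion Logical toggles for the four
#'   transform families.
#' @return The augmented sample.
#' @export
augment_sample <- function(sample, seed, crop = TRUE, rotation = TRUE,
                           flips = TRUE, distortion = TRUE) {
  with_seed(seed, {
    if (crop) {
      s <- stats::runif(1, 0.8, 1)
      sample <- crop_resize(sample, s, stats::runif(1), stats::runif(1))
    }
    if (rotation) sample <- rotate_sample(sample, stats::runif(1, -30, 30))
    if (flips) {
      if (stats::runif(1) < 0.5) sample <- flip_h(sample)
      if (stats::runif(1) < 0.5) sample <- flip_v(sample)
    }
    if (distortion) sample <- grid_distort(sample)
    sample
  })
}
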