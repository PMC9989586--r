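# Synthetic lesion-image generator: bright textured blobs with deformed
# elliptical outlines and blurred boundaries on a cluttered background,
# with the exact pre-blur blob support as ground-truth mask. This is what
# makes the whole pipeline testable without downloading clinical data.

.gauss_cache <- new.env(parent = emptyenv())

# Dense 1D Gaussian smoothing matrix (rows normalised); blur is then two
# matrix products, and is exactly reproducible.
gauss_matrix <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  g <- .gauss_cache[[key]]
  if (!is.null(g)) return(g)
  idx <- seq_len(n)
  g <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  g <- g / rowSums(g)
  .gauss_cache[[key]] <- g
  g
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  gauss_matrix(nrow(m), sigma) %*% m %*% t(gauss_matrix(ncol(m), sigma))
}

#' Parameters of the synthetic lesion generator
#'
#' Defaults emulate desk-scale polyp-like data: one to three bright blobs
#' covering roughly 10-30% of a 64x64 canvas, with smoothly deformed
#' elliptical outlines (radial deformation capped at `deform`), blurred
#' boundaries, low-frequency background clutter and pixel noise.
#'
#' @param image_size `c(height, width)` canvas.
#' @param n_blobs Integer range `c(min, max)` of blobs per image.
#' @param radius Range (pixels) of the base blob radius; the minimum must
#'   be at least 2.
#' @param contrast Blob brightness added over the background.
#' @param boundary_blur_sigma Gaussian sigma (pixels) of the boundary blur.
#' @param noise_sigma Pixelwise Gaussian noise sd.
#' @param texture_strength Amplitude of the smoothed background clutter.
#' @param deform Cap on the relative radial deformation of the outline
#'   (so the radius stays within `radius * (1 +/- deform)`).
#' @param channels 1 (grayscale) or 3 (RGB with slight channel tints).
#' @param seed Integer seed; the full dataset is a pure function of it.
#' @return List of class `gu_synth_params`.
#' @export
synthetic_params <- function(image_size = c(64L, 64L), n_blobs = c(1L, 3L),
                             radius = c(8, 14), contrast = 0.45,
                             boundary_blur_sigma = 1.5, noise_sigma = 0.05,
                             texture_strength = 0.15, deform = 0.25,
                             channels = 3L, seed = 1L) {
  stopifnot(radius[1] >= 2, noise_sigma >= 0, length(image_size) == 2,
            n_blobs[1] >= 0, deform >= 0, deform < 1)
  margin <- ceiling(radius[2] * (1 + deform)) + 1
  if (2 * margin >= min(image_size))
    stop("synthetic_params: blobs of radius ", radius[2],
         " cannot fit a ", image_size[1], "x", image_size[2], " canvas")
  structure(list(image_size = as.integer(image_size),
                 n_blobs = as.integer(n_blobs), radius = radius,
                 contrast = contrast,
                 boundary_blur_sigma = boundary_blur_sigma,
                 noise_sigma = noise_sigma,
                 texture_strength = texture_strength, deform = deform,
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "gu_synth_params")
}

# One blob: star-convex outline r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k)),
# with sum |a_k| <= deform. Returns the exact binary support.
blob_support <- function(H, W, center, r0, deform) {
  amp <- stats::runif(3, -1, 1)
  tot <- sum(abs(amp))
  if (tot > 0) amp <- amp * deform * stats::runif(1) / tot
  phase <- stats::runif(3, 0, 2 * pi)
  rr <- matrix(seq_len(H), H, W) - center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  dist <- sqrt(rr^2 + cc^2)
  theta <- atan2(cc, rr)
  rad <- r0 * (1 + amp[1] * cos(2 * theta + phase[1]) +
                 amp[2] * cos(3 * theta + phase[2]) +
                 amp[3] * cos(4 * theta + phase[3]))
  (dist <= rad) * 1
}

#' Generate synthetic segmentation samples
#'
#' Every sample is a pure function of `params$seed`, so two calls with
#' equal parameters are bitwise identical. Masks are the exact pre-blur
#' blob supports and are non-empty whenever `n_blobs >= 1`.
#'
#' @param n Number of samples.
#' @param params A [synthetic_params()] configuration.
#' @return List of [seg_sample()] objects.
#' @export
generate_synthetic <- function(n, params = synthetic_params()) {
  H <- params$image_size[1]; W <- params$image_size[2]
  margin <- ceiling(params$radius[2] * (1 + params$deform)) + 1
  with_seed(params$seed, {
    lapply(seq_len(n), function(i) {
      nb <- params$n_blobs[1] +
        sample.int(params$n_blobs[2] - params$n_blobs[1] + 1L, 1) - 1L
      support <- matrix(0, H, W)
      for (b in seq_len(nb)) {
        ctr <- c(stats::runif(1, margin, H - margin),
                 stats::runif(1, margin, W - margin))
        r0 <- stats::runif(1, params$radius[1], params$radius[2])
        support <- pmax(support, blob_support(H, W, ctr, r0, params$deform))
      }
      clutter <- gauss_blur(matrix(stats::rnorm(H * W), H, W), 3)
      clutter <- clutter / max(abs(clutter), 1e-8) * params$texture_strength
      body <- 0.35 + clutter +
        params$contrast * gauss_blur(support, params$boundary_blur_sigma)
      tints <- if (params$channels == 3L) c(1, 0.95, 0.88) else 1
      img <- vapply(tints, function(tt) {
        pmin(pmax(body * tt +
                    stats::rnorm(H * W, sd = params$noise_sigma), 0), 1)
      }, matrix(0, H, W))
      seg_sample(array(img, c(H, W, params$channels)), support,
                 sprintf("synth_%04d", i))
    })
  })
}
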