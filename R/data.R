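# Dataset handling: image/mask pairs, deterministic loading, resizing and
# splitting. Images are H x W x C arrays in [0,1]; masks are strictly
# binary H x W matrices.

#' Construct a segmentation sample
#'
#' @param image Numeric array `H x W x C` (a matrix is promoted to one
#'   channel) with values in \[0,1\].
#' @param mask Binary `H x W` matrix (values in \{0,1\}); anything else is
#'   binarised at 0.5.
#' @param id Character identifier.
#' @return Object of class `seg_sample`.
#' @export
seg_sample <- function(image, mask, id = "sample") {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  mask <- as.matrix(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("seg_sample: image and mask spatial sizes differ for '", id, "'")
  if (anyNA(image) || anyNA(mask))
    stop("seg_sample: missing values in '", id, "'")
  mask <- (mask >= 0.5) * 1
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "seg_sample")
}

#' @export
print.seg_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<seg_sample '%s': %dx%d, %d channel(s), foreground %.1f%%>\n",
              x$id, d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading '", path, "' requires the tiff package")
      tiff::readTIFF(path)
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading '", path, "' requires the jpeg package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: ", path)
  )
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Load matched image/mask pairs from two directories
#'
#' Files are paired by stem (filename without extension). Images are
#' decoded to \[0,1\]; single-channel images are replicated to three
#' channels; masks are binarised at 0.5 (so both 0/1 and 0/255 encodings
#' work). Samples are returned sorted by id, for determinism.
#'
#' @param image_dir,mask_dir Directories holding the images and the
#'   single-channel masks.
#' @return List of [seg_sample()] objects.
#' @export
load_pairs <- function(image_dir, mask_dir) {
  exts <- "\\.(png|tif|tiff|jpg|jpeg)$"
  ifiles <- sort(list.files(image_dir, pattern = exts, ignore.case = TRUE))
  mfiles <- sort(list.files(mask_dir, pattern = exts, ignore.case = TRUE))
  istem <- tools::file_path_sans_ext(ifiles)
  mstem <- tools::file_path_sans_ext(mfiles)
  only_i <- setdiff(istem, mstem)
  only_m <- setdiff(mstem, istem)
  if (length(only_i) || length(only_m))
    stop("load_pairs: unpaired files — images without masks: [",
         paste(only_i, collapse = ", "), "]; masks without images: [",
         paste(only_m, collapse = ", "), "]")
  if (anyDuplicated(istem) || anyDuplicated(mstem))
    stop("load_pairs: duplicated stems across extensions")
  ord <- order(istem)
  lapply(ord, function(i) {
    img <- read_image_file(file.path(image_dir, ifiles[i]))
    if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
    msk <- read_image_file(file.path(mask_dir,
                                     mfiles[match(istem[i], mstem)]))
    seg_sample(img, msk[, , 1], istem[i])
  })
}

# Nearest-neighbour index map n_out -> n_in (half-pixel centres).
nn_index <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pmin(pmax(round(src), 1L), n_in)
}

#' Resize a sample
#'
#' The image is resized bilinearly, the mask by nearest neighbour so it
#' stays strictly binary.
#'
#' @param sample A [seg_sample()].
#' @param size Target `c(height, width)`; default `c(320, 320)`.
#' @return A resized [seg_sample()].
#' @export
resize_sample <- function(sample, size = c(320L, 320L)) {
  d <- dim(sample$image)
  if (identical(as.integer(d[1:2]), as.integer(size)) ) return(sample)
  Uh <- interp_matrix(size[1], d[1])
  Uw <- interp_matrix(size[2], d[2])
  img <- interp_apply(as_batch(sample$image), Uh, Uw)
  img <- array(pmin(pmax(img, 0), 1), c(size, d[3]))
  msk <- sample$mask[nn_index(size[1], d[1]), nn_index(size[2], d[2])]
  seg_sample(img, msk, sample$id)
}

#' Deterministically split samples into train/validation/test sets
#'
#' Sizes are `floor(n*r_train)`, `floor(n*r_val)` and the remainder; the
#' permutation is drawn from `seed` without touching the global RNG
#' stream, so the split is reproducible and the three sets are disjoint
#' and exhaustive.
#'
#' @param samples List of samples (any list).
#' @param ratios Numeric triple summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` sub-lists.
#' @export
split_samples <- function(samples, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-8)
  n <- length(samples)
  perm <- with_seed(seed, sample.int(n))
  n1 <- floor(n * ratios[1])
  n2 <- floor(n * ratios[2])
  list(train = samples[perm[seq_len(n1)]],
       val = samples[perm[n1 + seq_len(n2)]],
       test = samples[perm[setdiff(seq_len(n), seq_len(n1 + n2))]])
}

#' Write samples to an images/ + masks/ directory layout
#'
#' Images and masks are written as PNG (masks 0/1 scaled to 0/255), plus
#' a `manifest.csv` with one row per sample id.
#'
#' @param samples List of [seg_sample()] objects.
#' @param dir Output directory (created if needed).
#' @param split Optional character vector of split labels recorded in the
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    png::writePNG(s$mask, file.path(dir, "masks", paste0(s$id, ".png")))
  }
  man <- data.frame(id = vapply(samples, `[[`, "", "id"),
                    split = if (is.null(split)) "all" else split)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
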