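# Intensity normalisation, patch sampling (random + label-guided cropping
# against class imbalance), and augmentation.
#
# Conventions: images are (C, X, Y, Z) arrays, labels (X, Y, Z) integer arrays
# aligned to the image; crop origins are 0-based voxel coordinates.

#' Percentile intensity normalisation to [0, 1]
#'
#' Per channel, the 5th and 95th percentiles of the foreground intensities
#' (foreground = strictly nonzero voxels, the skull-stripped convention) define
#' an affine map `x -> (x - p5) / (p95 - p5)` applied to every voxel and
#' clipped to `[0, 1]`.
#'
#' @param vol (C, X, Y, Z) intensity array.
#' @param probs lower/upper percentiles (defaults 0.05, 0.95).
#' @return array of the same shape with all values in `[0, 1]`.
#' @export
normaliseIntensity <- function(vol, probs = c(0.05, 0.95)) {
  if (length(dim(vol)) != 4L) stop("expected a (C, X, Y, Z) array", call. = FALSE)
  out <- vol
  for (c in seq_len(dim(vol)[1L])) {
    v <- vol[c, , , ]
    fg <- v[v != 0]
    if (length(fg) == 0L)
      stop("channel ", c, " is all zero: no foreground to compute percentiles from",
           call. = FALSE)
    q <- quantile(fg, probs, names = FALSE, type = 7)
    if (q[2L] <= q[1L])
      stop("degenerate intensity range in channel ", c, " (p", 100 * probs[1L],
           " == p", 100 * probs[2L], " = ", q[1L], ")", call. = FALSE)
    out[c, , , ] <- pmin(pmax((v - q[1L]) / (q[2L] - q[1L]), 0), 1)
  }
  out
}

.check_crop <- function(vshape, size) {
  if (any(size > vshape))
    stop("crop size (", paste(size, collapse = "x"), ") exceeds volume (",
         paste(vshape, collapse = "x"), "); pad the volume first", call. = FALSE)
}

.extract_patch <- function(vol, labels, origin, size) {
  ix <- (origin[1L] + 1L):(origin[1L] + size[1L])
  iy <- (origin[2L] + 1L):(origin[2L] + size[2L])
  iz <- (origin[3L] + 1L):(origin[3L] + size[3L])
  list(image = vol[, ix, iy, iz, drop = FALSE],
       labels = labels[ix, iy, iz, drop = FALSE],
       origin = as.integer(origin))
}

#' Uniform random crop
#'
#' The origin is uniform over all positions at which the patch fits entirely
#' inside the volume; image and labels are cropped identically.
#'
#' @param vol (C, X, Y, Z) image array.
#' @param labels (X, Y, Z) label array.
#' @param size integer patch size per axis (recycled to length 3).
#' @return list with `image`, `labels` and the 0-based `origin`.
#' @export
randomCrop <- function(vol, labels, size) {
  size <- rep_len(as.integer(size), 3L)
  vshape <- dim(vol)[-1L]
  if (!identical(vshape, dim(labels))) stop("image and label shapes differ", call. = FALSE)
  .check_crop(vshape, size)
  origin <- vapply(1:3, function(a) sample.int(vshape[a] - size[a] + 1L, 1L) - 1L, 0L)
  .extract_patch(vol, labels, origin, size)
}

#' Label-guided crop
#'
#' A foreground (label > 0) voxel is chosen uniformly; the patch is centred on
#' it with the origin clipped to the volume bounds, so the patch always
#' contains at least one foreground voxel.
#'
#' @inheritParams randomCrop
#' @return list with `image`, `labels` and the 0-based `origin`.
#' @export
labelGuidedCrop <- function(vol, labels, size) {
  size <- rep_len(as.integer(size), 3L)
  vshape <- dim(vol)[-1L]
  if (!identical(vshape, dim(labels))) stop("image and label shapes differ", call. = FALSE)
  .check_crop(vshape, size)
  fg <- which(labels > 0)
  if (length(fg) == 0L)
    stop("label map has no foreground voxel; fall back to randomCrop()", call. = FALSE)
  pick <- fg[sample.int(length(fg), 1L)]
  centre <- arrayInd(pick, dim(labels))[1L, ]
  origin <- pmin(pmax(centre - 1L - size %/% 2L, 0L), vshape - size)
  .extract_patch(vol, labels, as.integer(origin), size)
}

# ---- spatial ops (applied jointly to image and labels) -----------------------

#' Flip a patch along a spatial axis
#'
#' @param pair list with `image` (C, X, Y, Z) and `labels` (X, Y, Z).
#' @param axis spatial axis 1..3.
#' @return the flipped pair (an involution: flipping twice restores the input).
#' @export
flipPatch <- function(pair, axis) {
  d <- dim(pair$labels)
  idx <- rev(seq_len(d[axis]))
  args_im <- rep(list(quote(expr = )), 4L); args_im[[axis + 1L]] <- idx
  args_lb <- rep(list(quote(expr = )), 3L); args_lb[[axis]] <- idx
  pair$image <- do.call(`[`, c(list(pair$image), args_im, list(drop = FALSE)))
  pair$labels <- do.call(`[`, c(list(pair$labels), args_lb, list(drop = FALSE)))
  pair
}

#' Rotate a patch by 90 degrees in an orthogonal plane
#'
#' @param pair list with `image` and `labels`.
#' @param plane spatial axis pair, one of `c(1,2)`, `c(1,3)`, `c(2,3)`.
#' @param k number of successive 90-degree rotations.
#' @return the rotated pair (labels move with the image; no interpolation).
#' @export
rotatePatch90 <- function(pair, plane = c(1L, 2L), k = 1L) {
  plane <- sort(as.integer(plane))
  for (r in seq_len(((k %% 4L) + 4L) %% 4L)) {
    perm3 <- 1:3; perm3[plane] <- rev(plane)
    pair$labels <- aperm(pair$labels, perm3)
    pair$image <- aperm(pair$image, c(1L, perm3 + 1L))
    pair <- flipPatch(pair, plane[1L])
  }
  pair
}

#' Random training augmentation
#'
#' Spatial ops — per-axis flips and 90-degree rotations in the three
#' orthogonal planes — are applied jointly to image and labels (labels move as
#' permutations, no interpolation). Intensity ops — multiplicative scaling,
#' additive shift, Gaussian noise — touch the image only.
#'
#' @param pair list with `image` and `labels` from a cropping function.
#' @param cfg augmentation configuration, see [augmentConfig()].
#' @return augmented pair.
#' @export
augmentPatch <- function(pair, cfg = augmentConfig()) {
  for (axis in 1:3)
    if (runif(1) < cfg$p_flip) pair <- flipPatch(pair, axis)
  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (pl in planes)
    if (runif(1) < cfg$p_rot90) pair <- rotatePatch90(pair, pl, k = sample.int(3L, 1L))
  if (runif(1) < cfg$p_scale)
    pair$image <- pair$image * (1 + runif(1, -cfg$scale_range, cfg$scale_range))
  if (runif(1) < cfg$p_shift)
    pair$image <- pair$image + runif(1, -cfg$shift_range, cfg$shift_range)
  if (runif(1) < cfg$p_noise)
    pair$image <- pair$image + array(rnorm(length(pair$image), sd = cfg$noise_sd),
                                     dim = dim(pair$image))
  pair
}

#' Augmentation configuration
#'
#' @param p_flip per-axis flip probability.
#' @param p_rot90 per-plane 90-degree rotation probability.
#' @param p_scale,scale_range probability and half-range of multiplicative
#'   intensity scaling `x -> x * (1 + u)`, `u ~ U(-range, range)`.
#' @param p_shift,shift_range probability and half-range of additive shift.
#' @param p_noise,noise_sd probability and standard deviation of added
#'   Gaussian noise.
#' @return validated configuration list.
#' @export
augmentConfig <- function(p_flip = 0.5, p_rot90 = 0.5,
                          p_scale = 1.0, scale_range = 0.1,
                          p_shift = 1.0, shift_range = 0.1,
                          p_noise = 0.15, noise_sd = 0.01) {
  cfg <- list(p_flip = p_flip, p_rot90 = p_rot90, p_scale = p_scale,
              scale_range = scale_range, p_shift = p_shift,
              shift_range = shift_range, p_noise = p_noise, noise_sd = noise_sd)
  probs <- unlist(cfg[c("p_flip", "p_rot90", "p_scale", "p_shift", "p_noise")])
  if (any(probs < 0 | probs > 1)) stop("augmentation probabilities must be in [0, 1]", call. = FALSE)
  cfg
}

#' Tumour-region voxel fraction of a label map
#'
#' @param labels (X, Y, Z) label array in BraTS convention.
#' @param region one of `"WT"`, `"TC"`, `"ET"`.
#' @return fraction of volume voxels belonging to the region, in `[0, 1]`.
#' @export
tumourRatio <- function(labels, region = c("WT", "TC", "ET")) {
  region <- match.arg(region)
  mask <- regionsFromLabels(labels)[[region]]
  sum(mask) / length(mask)
}
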