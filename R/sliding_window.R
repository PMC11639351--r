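# Sliding-window inference: tile the volume into ROI-sized windows at a stride
# set by the overlap fraction, forward each window, and blend the per-voxel
# probabilities with either uniform or Gaussian importance weights.

#' Plan sliding windows over a volume
#'
#' Per axis the stride is `max(1, round(roi * (1 - overlap)))`; origins follow
#' that arithmetic progression and the last window is clamped flush to the
#' boundary, so every voxel is covered by at least one window.
#'
#' @param volume_shape (X, Y, Z) volume shape.
#' @param roi window size per axis (recycled to length 3).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list with `roi`, `overlap` and `origins`, an n x 3 matrix of 0-based
#'   window corner coordinates.
#' @export
planWindows <- function(volume_shape, roi, overlap = 0.5) {
  volume_shape <- as.integer(volume_shape)
  roi <- rep_len(as.integer(roi), 3L)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  if (any(roi > volume_shape))
    stop("roi (", paste(roi, collapse = "x"), ") exceeds volume (",
         paste(volume_shape, collapse = "x"), "); pad the volume first", call. = FALSE)
  axis_starts <- lapply(1:3, function(a) {
    stride <- max(1L, as.integer(round(roi[a] * (1 - overlap))))
    s <- seq.int(0L, volume_shape[a] - roi[a], by = stride)
    unique(c(s, volume_shape[a] - roi[a]))
  })
  origins <- as.matrix(expand.grid(axis_starts[[1L]], axis_starts[[2L]], axis_starts[[3L]]))
  dimnames(origins) <- NULL
  list(roi = roi, overlap = overlap, origins = origins)
}

#' Gaussian importance map for window blending
#'
#' A separable Gaussian centred on the window, peak-normalised to 1 and floored
#' at 1e-3 of the peak so no voxel weight is zero; central voxels (which see
#' full spatial context) thus dominate the blend over window-edge voxels.
#'
#' @param roi window shape per axis.
#' @param sigma_scale Gaussian sigma as a fraction of the window size per axis.
#' @return array of shape `roi`, strictly positive, maximum 1, symmetric under
#'   reflection of any axis.
#' @export
gaussianImportanceMap <- function(roi, sigma_scale = 0.125) {
  roi <- rep_len(as.integer(roi), 3L)
  if (any(roi < 1L)) stop("roi must be positive", call. = FALSE)
  if (sigma_scale <= 0) stop("sigma_scale must be positive", call. = FALSE)
  ax <- lapply(1:3, function(a) {
    i <- seq_len(roi[a]) - 1
    ctr <- (roi[a] - 1) / 2
    exp(-0.5 * ((i - ctr) / (sigma_scale * roi[a]))^2)
  })
  m <- outer(outer(ax[[1L]], ax[[2L]]), ax[[3L]])
  dim(m) <- roi
  m <- m / max(m)
  pmax(m, 1e-3)
}

.as_predict_fn <- function(model) {
  if (is.function(model)) return(model)
  if (is(model, "TCTNetModel")) return(function(patch) tctnetForward(patch = patch, model = model))
  stop("model must be a TCTNetModel or a function(patch) -> probability array", call. = FALSE)
}

#' Sliding-window inference over a full volume
#'
#' Accumulates `weight * probability` and `weight` per voxel over all windows
#' and divides, blending in probability space. With `use_gaussian = FALSE` the
#' weight is uniform. Volumes smaller than the ROI are symmetrically
#' zero-padded and the output cropped back.
#'
#' @param vol (C, X, Y, Z) normalised intensity array.
#' @param model a [TCTNetModel-class] or a `function(patch)` returning a
#'   (n_classes, roi) probability array.
#' @param roi window size (the training crop size).
#' @param overlap fractional window overlap.
#' @param use_gaussian use the Gaussian importance map (`TRUE`) or uniform
#'   weights (`FALSE`).
#' @param sigma_scale Gaussian width, see [gaussianImportanceMap()].
#' @return (n_classes, X, Y, Z) probability array summing to 1 per voxel.
#' @export
slidingWindowInfer <- function(vol, model, roi, overlap = 0.5, use_gaussian = TRUE,
                               sigma_scale = 0.125) {
  fn <- .as_predict_fn(model)
  roi <- rep_len(as.integer(roi), 3L)
  vshape <- dim(vol)[-1L]
  pad_lo <- pmax((roi - vshape) %/% 2L, 0L)
  pad_hi <- pmax(roi - vshape - pad_lo, 0L)
  if (any(pad_lo > 0L | pad_hi > 0L)) {
    padded <- array(0, dim = c(dim(vol)[1L], vshape + pad_lo + pad_hi))
    padded[, pad_lo[1L] + seq_len(vshape[1L]), pad_lo[2L] + seq_len(vshape[2L]),
           pad_lo[3L] + seq_len(vshape[3L])] <- vol
    out <- slidingWindowInfer(padded, fn, roi, overlap, use_gaussian, sigma_scale)
    return(out[, pad_lo[1L] + seq_len(vshape[1L]), pad_lo[2L] + seq_len(vshape[2L]),
               pad_lo[3L] + seq_len(vshape[3L]), drop = FALSE])
  }
  plan <- planWindows(vshape, roi, overlap)
  w <- if (use_gaussian) gaussianImportanceMap(roi, sigma_scale) else array(1, dim = roi)
  acc <- NULL
  wacc <- array(0, dim = vshape)
  for (r in seq_len(nrow(plan$origins))) {
    o <- plan$origins[r, ]
    ix <- o[1L] + seq_len(roi[1L]); iy <- o[2L] + seq_len(roi[2L]); iz <- o[3L] + seq_len(roi[3L])
    probs <- fn(vol[, ix, iy, iz, drop = FALSE])
    if (!identical(dim(probs)[-1L], roi))
      stop("model output spatial shape (", paste(dim(probs)[-1L], collapse = "x"),
           ") does not match roi", call. = FALSE)
    if (is.null(acc)) acc <- array(0, dim = c(dim(probs)[1L], vshape))
    wb <- array(rep(w, each = dim(probs)[1L]), dim = dim(probs))
    acc[, ix, iy, iz] <- acc[, ix, iy, iz] + wb * probs
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + w
  }
  acc / array(rep(wacc, each = dim(acc)[1L]), dim = dim(acc))
}

#' Trilinear resize of a channel-first volume
#'
#' @param vol (C, X, Y, Z) array.
#' @param new_shape target (X, Y, Z) shape.
#' @return resized (C, new_shape) array (align-corners = FALSE convention).
#' @export
trilinearResize <- function(vol, new_shape) {
  new_shape <- as.integer(rep_len(new_shape, 3L))
  old <- dim(vol)[-1L]
  C <- dim(vol)[1L]
  coords <- lapply(1:3, function(a) {
    src <- ((seq_len(new_shape[a]) - 0.5) * old[a] / new_shape[a]) - 0.5
    lo <- pmin(pmax(floor(src), 0), old[a] - 1)
    hi <- pmin(lo + 1, old[a] - 1)
    list(lo = lo + 1, hi = hi + 1, t = pmin(pmax(src - lo, 0), 1))
  })
  out <- array(0, dim = c(C, new_shape))
  tx <- coords[[1L]]$t; ty <- coords[[2L]]$t; tz <- coords[[3L]]$t
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- if (dx == 0) coords[[1L]]$lo else coords[[1L]]$hi
    iy <- if (dy == 0) coords[[2L]]$lo else coords[[2L]]$hi
    iz <- if (dz == 0) coords[[3L]]$lo else coords[[3L]]$hi
    wx <- if (dx == 0) 1 - tx else tx
    wy <- if (dy == 0) 1 - ty else ty
    wz <- if (dz == 0) 1 - tz else tz
    wgt <- outer(outer(wx, wy), wz)
    sub <- vol[, ix, iy, iz, drop = FALSE]
    out <- out + sub * array(rep(wgt, each = C), dim = c(C, new_shape))
  }
  out
}

#' Resize-twice inference baseline
#'
#' Downsamples the whole volume to the ROI, forwards it once, and upsamples
#' the probabilities back — the comparison mode that sliding-window inference
#' with overlap and Gaussian weighting supersedes.
#'
#' @inheritParams slidingWindowInfer
#' @return (n_classes, X, Y, Z) probability array (renormalised per voxel
#'   after interpolation).
#' @export
resizeTwiceInfer <- function(vol, model, roi) {
  fn <- .as_predict_fn(model)
  roi <- rep_len(as.integer(roi), 3L)
  small <- trilinearResize(vol, roi)
  probs <- fn(small)
  up <- trilinearResize(probs, dim(vol)[-1L])
  s <- apply(up, c(2L, 3L, 4L), sum)
  up / array(rep(s, each = dim(up)[1L]), dim = dim(up))
}
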