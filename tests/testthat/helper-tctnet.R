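# Shared fixtures and independent oracles for the test suite.

# small network configuration used throughout the tests
tiny_config <- function(in_channels = 2L, seed = 7L, ...) {
  modelConfig(in_channels = in_channels, n_classes = 4L, stem_width = 8L,
              stage_widths = c(8L, 16L, 32L, 64L), head_width = 4L, seed = seed, ...)
}

# the published full-scale configuration
published_config <- function() modelConfig()

# independent dense-loop attention oracle: explicit three-loop softmax attention
naive_attention <- function(Q, K, V, heads) {
  C <- ncol(Q); d <- C / heads
  out <- matrix(0, nrow(Q), C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * d + 1):(h * d)
    for (i in seq_len(nrow(Q))) {
      logits <- numeric(nrow(K))
      for (j in seq_len(nrow(K)))
        logits[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(d)
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      for (j in seq_len(nrow(K)))
        out[i, cols] <- out[i, cols] + w[j] * V[j, cols]
    }
  }
  out
}

# independent naive sliding-window blender: per-window, per-voxel loops
naive_sliding_window <- function(vol, fn, roi, overlap, weight) {
  vshape <- dim(vol)[-1L]
  plan <- planWindows(vshape, roi, overlap)
  probe <- fn(vol[, 1:roi[1], 1:roi[2], 1:roi[3], drop = FALSE])
  C <- dim(probe)[1L]
  acc <- array(0, dim = c(C, vshape))
  wsum <- array(0, dim = vshape)
  for (r in seq_len(nrow(plan$origins))) {
    o <- plan$origins[r, ]
    patch <- vol[, o[1] + 1:roi[1], o[2] + 1:roi[2], o[3] + 1:roi[3], drop = FALSE]
    p <- fn(patch)
    for (i in 1:roi[1]) for (j in 1:roi[2]) for (k in 1:roi[3]) {
      acc[, o[1] + i, o[2] + j, o[3] + k] <- acc[, o[1] + i, o[2] + j, o[3] + k] +
        weight[i, j, k] * p[, i, j, k]
      wsum[o[1] + i, o[2] + j, o[3] + k] <- wsum[o[1] + i, o[2] + j, o[3] + k] + weight[i, j, k]
    }
  }
  for (c in seq_len(C)) acc[c, , , ] <- acc[c, , , ] / wsum
  acc
}

# finite-difference gradient relative error on a random sample of entries
fd_relerr <- function(loss_grad_fn, x, n = 10L, eps = 1e-6) {
  r <- loss_grad_fn(x)
  idx <- sample(length(x), min(n, length(x)))
  worst <- 0
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    gnum <- (loss_grad_fn(xp)$loss - loss_grad_fn(xm)$loss) / (2 * eps)
    worst <- max(worst, abs(gnum - r$grad[i]) / max(1e-5, abs(gnum), abs(r$grad[i])))
  }
  worst
}

# small phantom families used by the training tests
small_phantom <- function(seed = 11L, shape = c(32L, 32L, 32L), radius = c(6, 8)) {
  generatePhantom(phantomSpec(shape = shape, lesion_radius_range = radius, seed = seed))
}
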