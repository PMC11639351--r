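# Decoder: 3D direction-wise convolution blocks at every scale (including the
# original scale), transposed-conv upsampling with residual fusion of skip
# features, and a 1x1x1 softmax segmentation head.

# the 6 orderings of the X, Y, Z axes, one per sub-path
.axis_perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Initialise a 3D direction-wise convolution block
#'
#' The block has 6 sub-paths, one per permutation of the spatial axes; each
#' sub-path applies three uni-directional depth-wise convolutions (kernels
#' a x 1 x 1, 1 x a x 1, 1 x 1 x a in its axis order). Sub-path outputs are
#' concatenated, projected back to `channels` by a pointwise convolution,
#' layer-normalised, added to the input, and passed through GELU.
#'
#' @param channels feature channels of the block input (and output).
#' @param kernel_length odd length `a` of the uni-directional kernels.
#' @param seed optional RNG seed for the weight draw.
#' @return parameter list consumed by [dwConvBlock()].
#' @export
dwConvBlockInit <- function(channels, kernel_length = 7L, seed = NULL) {
  if (kernel_length %% 2L != 1L) stop("kernel_length must be odd", call. = FALSE)
  make <- function() {
    paths <- lapply(1:6, function(s) {
      lapply(1:3, function(j) {
        kern <- rep(1L, 3L)
        kern[.axis_perms[s, j]] <- as.integer(kernel_length)
        .init_conv(channels, channels, kern, groups = channels)
      })
    })
    list(paths = paths,
         proj = .init_conv(6L * channels, channels, 1L),
         ln = .init_ln(channels))
  }
  if (is.null(seed)) make() else .with_seed(seed, make())
}

.dw_fwd <- function(x, p, keep_cache = TRUE) {
  C <- dim(x)[1L]
  if (dim(p$proj$w)[2L] != 6L * C)
    stop("direction-wise block expects ", dim(p$proj$w)[2L] %/% 6L,
         " channels, got ", C, call. = FALSE)
  sp <- dim(x)[-1L]
  cat_arr <- array(0, dim = c(6L * C, sp))
  pcaches <- vector("list", 6L)
  for (s in 1:6) {
    h <- x
    cc <- vector("list", 3L)
    for (j in 1:3) {
      kern <- dim(p$paths[[s]][[j]]$w)[3:5]
      cv <- .conv_fwd(h, p$paths[[s]][[j]], stride = 1L, pad = (kern - 1L) %/% 2L,
                      groups = C, name = "dw_uniconv")
      h <- cv$y
      cc[[j]] <- cv$cache
    }
    cat_arr[((s - 1L) * C + 1L):(s * C), , , ] <- h
    pcaches[[s]] <- cc
  }
  pr <- .conv_fwd(cat_arr, p$proj, stride = 1L, pad = 0L, name = "dw_proj")
  ln <- .ln_fwd(.to_tokens(pr$y), p$ln)
  pre <- x + .to_array(ln$y, sp)
  ge <- .gelu_fwd(pre)
  list(y = ge$y,
       cache = if (keep_cache) list(paths = pcaches, proj = pr$cache, ln = ln$cache,
                                    pre = ge$cache, sp = sp, C = C))
}

.dw_bwd <- function(p, cache, gy) {
  C <- cache$C; sp <- cache$sp
  gpre <- .gelu_bwd(cache$pre, gy)
  lnb <- .ln_bwd(p$ln, cache$ln, .to_tokens(gpre))
  prb <- .conv_bwd(p$proj, cache$proj, .to_array(lnb$gx, sp))
  gx <- gpre
  pgrads <- vector("list", 6L)
  for (s in 1:6) {
    g <- array(prb$gx[((s - 1L) * C + 1L):(s * C), , , ], dim = c(C, sp))
    cg <- vector("list", 3L)
    for (j in 3:1) {
      cb <- .conv_bwd(p$paths[[s]][[j]], cache$paths[[s]][[j]], g)
      g <- cb$gx
      cg[[j]] <- cb$grads
    }
    gx <- gx + g
    pgrads[[s]] <- cg
  }
  list(gx = gx, grads = list(paths = pgrads, proj = prb$grads, ln = lnb$grads))
}

#' Apply a 3D direction-wise convolution block
#'
#' @param fm feature map, a (channels, X, Y, Z) array.
#' @param params block parameters from [dwConvBlockInit()].
#' @return array of the same shape as `fm`.
#' @export
dwConvBlock <- function(fm, params) {
  r <- .dw_fwd(fm, params, keep_cache = FALSE)
  out <- r$y
  attributes(out) <- attributes(fm)
  dim(out) <- dim(fm)
  out
}

# ---- residual fusion of upsampled features with a skip connection -----------

.init_fuse <- function(c_low, c_skip) {
  list(up = .init_convt(c_low, c_skip, 2L),
       conv1 = .init_conv(2L * c_skip, c_skip, 3L), ln1 = .init_ln(c_skip),
       conv2 = .init_conv(c_skip, c_skip, 3L), ln2 = .init_ln(c_skip),
       short = .init_conv(2L * c_skip, c_skip, 1L))
}

# plain residual block (same interface as .dw_fwd) for the block-swap ablation
.init_resblock <- function(C) {
  list(conv1 = .init_conv(C, C, 3L), ln1 = .init_ln(C),
       conv2 = .init_conv(C, C, 3L), ln2 = .init_ln(C))
}

.res_fwd <- function(x, p, keep_cache = TRUE) {
  sp <- dim(x)[-1L]
  c1 <- .conv_fwd(x, p$conv1, stride = 1L, pad = 1L, name = "res_conv")
  l1 <- .ln_fwd(.to_tokens(c1$y), p$ln1)
  g1 <- .gelu_fwd(l1$y)
  c2 <- .conv_fwd(.to_array(g1$y, sp), p$conv2, stride = 1L, pad = 1L, name = "res_conv")
  l2 <- .ln_fwd(.to_tokens(c2$y), p$ln2)
  pre <- x + .to_array(l2$y, sp)
  ge <- .gelu_fwd(pre)
  list(y = ge$y,
       cache = if (keep_cache) list(c1 = c1$cache, l1 = l1$cache, g1 = g1$cache,
                                    c2 = c2$cache, l2 = l2$cache, pre = ge$cache, sp = sp))
}

.res_bwd <- function(p, cache, gy) {
  sp <- cache$sp
  gpre <- .gelu_bwd(cache$pre, gy)
  l2b <- .ln_bwd(p$ln2, cache$l2, .to_tokens(gpre))
  c2b <- .conv_bwd(p$conv2, cache$c2, .to_array(l2b$gx, sp))
  g1b <- .gelu_bwd(cache$g1, .to_tokens(c2b$gx))
  l1b <- .ln_bwd(p$ln1, cache$l1, g1b)
  c1b <- .conv_bwd(p$conv1, cache$c1, .to_array(l1b$gx, sp))
  list(gx = gpre + c1b$gx,
       grads = list(conv1 = c1b$grads, ln1 = l1b$grads,
                    conv2 = c2b$grads, ln2 = l2b$grads))
}

.fuse_fwd <- function(low, skip, p, keep_cache = TRUE) {
  sl <- attr(low, "stage_scale"); ss <- attr(skip, "stage_scale")
  if (!is.null(sl) && !is.null(ss) && sl != 2L * ss)
    stop("fusion expects low at exactly 2x the skip scale (got ", sl, " vs ", ss, ")",
         call. = FALSE)
  up <- .convt_fwd(low, p$up, 2L, name = "fuse_up")
  if (!identical(dim(up$y)[-1L], dim(skip)[-1L]))
    stop("upsampled feature shape ", paste(dim(up$y)[-1L], collapse = "x"),
         " does not match skip ", paste(dim(skip)[-1L], collapse = "x"), call. = FALSE)
  cs <- dim(skip)[1L]
  sp <- dim(skip)[-1L]
  cat_arr <- array(0, dim = c(2L * cs, sp))
  cat_arr[1:cs, , , ] <- up$y
  cat_arr[(cs + 1L):(2L * cs), , , ] <- skip
  c1 <- .conv_fwd(cat_arr, p$conv1, stride = 1L, pad = 1L, name = "fuse_conv")
  l1 <- .ln_fwd(.to_tokens(c1$y), p$ln1)
  g1 <- .gelu_fwd(l1$y)
  c2 <- .conv_fwd(.to_array(g1$y, sp), p$conv2, stride = 1L, pad = 1L, name = "fuse_conv")
  l2 <- .ln_fwd(.to_tokens(c2$y), p$ln2)
  sc <- .conv_fwd(cat_arr, p$short, stride = 1L, pad = 0L, name = "fuse_short")
  pre <- .to_array(l2$y, sp) + sc$y
  ge <- .gelu_fwd(pre)
  y <- structure(ge$y, stage_scale = ss)
  list(y = y,
       cache = if (keep_cache) list(up = up$cache, c1 = c1$cache, l1 = l1$cache,
                                    g1 = g1$cache, c2 = c2$cache, l2 = l2$cache,
                                    sc = sc$cache, pre = ge$cache, sp = sp, cs = cs))
}

.fuse_bwd <- function(p, cache, gy) {
  sp <- cache$sp; cs <- cache$cs
  gpre <- .gelu_bwd(cache$pre, gy)
  scb <- .conv_bwd(p$short, cache$sc, gpre)
  l2b <- .ln_bwd(p$ln2, cache$l2, .to_tokens(gpre))
  c2b <- .conv_bwd(p$conv2, cache$c2, .to_array(l2b$gx, sp))
  g1b <- .gelu_bwd(cache$g1, .to_tokens(c2b$gx))
  l1b <- .ln_bwd(p$ln1, cache$l1, g1b)
  c1b <- .conv_bwd(p$conv1, cache$c1, .to_array(l1b$gx, sp))
  gcat <- scb$gx + c1b$gx
  gup <- array(gcat[1:cs, , , ], dim = c(cs, sp))
  gskip <- array(gcat[(cs + 1L):(2L * cs), , , ], dim = c(cs, sp))
  upb <- .convt_bwd(p$up, cache$up, gup)
  list(glow = upb$gx, gskip = gskip,
       grads = list(up = upb$grads, conv1 = c1b$grads, ln1 = l1b$grads,
                    conv2 = c2b$grads, ln2 = l2b$grads, short = scb$grads))
}

# ---- decoder assembly --------------------------------------------------------

.init_decoder <- function(cfg) {
  w <- cfg$stage_widths
  hw <- cfg$head_width
  block_init <- function(C) {
    if (identical(cfg$decoder_block, "residual")) .init_resblock(C)
    else dwConvBlockInit(C, cfg$dw_kernel_length)
  }
  list(fuse = list(.init_fuse(w[4L], w[3L]), .init_fuse(w[3L], w[2L]), .init_fuse(w[2L], w[1L])),
       blocks = list(block_init(w[3L]), block_init(w[2L]), block_init(w[1L]), block_init(hw)),
       finalup = .init_convt(w[1L], hw, 2L),
       head = .init_conv(hw, cfg$n_classes, 1L))
}

.check_pyramid <- function(pyramid) {
  if (!is.list(pyramid) || length(pyramid) != 4L)
    stop("feature pyramid must hold 4 levels at scales 2, 4, 8, 16", call. = FALSE)
  for (i in 1:4) {
    sc <- attr(pyramid[[i]], "stage_scale")
    if (is.null(pyramid[[i]]) || (!is.null(sc) && sc != 2L^i))
      stop("pyramid level ", i, " missing or not at scale ", 2L^i, call. = FALSE)
  }
  invisible(TRUE)
}

.decoder_fwd <- function(params, pyramid, cfg, keep_cache = FALSE) {
  .check_pyramid(pyramid)
  block_fwd <- if (identical(cfg$decoder_block, "residual")) .res_fwd else .dw_fwd
  x <- pyramid[[4L]]
  fcaches <- vector("list", 3L)
  bcaches <- vector("list", 4L)
  n_blocks <- 0L
  for (j in 1:3) {
    f <- .fuse_fwd(x, pyramid[[4L - j]], params$fuse[[j]], keep_cache)
    d <- block_fwd(f$y, params$blocks[[j]], keep_cache)
    x <- structure(d$y, stage_scale = attr(f$y, "stage_scale"))
    n_blocks <- n_blocks + 1L
    if (keep_cache) { fcaches[[j]] <- f$cache; bcaches[[j]] <- d$cache }
  }
  fu <- .convt_fwd(x, params$finalup, 2L, name = "final_up")
  d4 <- block_fwd(fu$y, params$blocks[[4L]], keep_cache)
  if (keep_cache) bcaches[[4L]] <- d4$cache
  n_blocks <- n_blocks + 1L
  hd <- .conv_fwd(d4$y, params$head, stride = 1L, pad = 0L, name = "head")
  logits <- structure(hd$y, stage_scale = 1L)
  list(logits = logits, n_blocks = n_blocks,
       cache = if (keep_cache) list(fuse = fcaches, blocks = bcaches,
                                    fu = fu$cache, hd = hd$cache))
}

.decoder_bwd <- function(params, cache, glogits, cfg) {
  block_bwd <- if (identical(cfg$decoder_block, "residual")) .res_bwd else .dw_bwd
  hdb <- .conv_bwd(params$head, cache$hd, glogits)
  d4b <- block_bwd(params$blocks[[4L]], cache$blocks[[4L]], hdb$gx)
  fub <- .convt_bwd(params$finalup, cache$fu, d4b$gx)
  g <- fub$gx
  gpyramid <- vector("list", 4L)
  fgrads <- vector("list", 3L)
  bgrads <- vector("list", 4L)
  bgrads[[4L]] <- d4b$grads
  for (j in 3:1) {
    db <- block_bwd(params$blocks[[j]], cache$blocks[[j]], g)
    fb <- .fuse_bwd(params$fuse[[j]], cache$fuse[[j]], db$gx)
    gpyramid[[4L - j]] <- fb$gskip
    g <- fb$glow
    bgrads[[j]] <- db$grads
    fgrads[[j]] <- fb$grads
  }
  gpyramid[[4L]] <- g
  list(gpyramid = gpyramid,
       grads = list(fuse = fgrads, blocks = bgrads, finalup = fub$grads, head = hdb$grads))
}

#' Softmax segmentation head
#'
#' Applies a 1x1x1 convolution followed by a per-voxel softmax over classes.
#'
#' @param fm feature map (C, X, Y, Z) at the original scale
#'   (`stage_scale` attribute 1, if present).
#' @param params list with `w` (n_classes, C, 1, 1, 1 array) and `b`.
#' @return (n_classes, X, Y, Z) array of per-voxel class probabilities.
#' @export
segmentationHead <- function(fm, params) {
  sc <- attr(fm, "stage_scale")
  if (!is.null(sc) && sc != 1L)
    stop("segmentation head requires features at the original scale (stage_scale 1), got ",
         sc, call. = FALSE)
  hd <- .conv_fwd(fm, params, stride = 1L, pad = 0L, name = "head")
  .softmax_channels(hd$y)
}
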