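# Four-stage hybrid Transformer-CNN encoder.
#
# Stem: 7x7x7 conv, stride 2, pad 3, layer norm + GELU, feeding stage 1 at 1/2
# resolution. Between stages a non-overlapping 2x2x2 stride-2 convolutional
# patch embedding halves resolution, giving the 1/2, 1/4, 1/8, 1/16 ladder.
# With K/V reduction rates (8, 4, 2, 1) the attention key/value grid then has
# the same size (input/32 per axis) at every stage.

.init_encoder <- function(cfg) {
  w <- cfg$stage_widths
  stages <- vector("list", 4L)
  for (i in 1:4) {
    embed <- if (i > 1L)
      list(conv = .init_conv(w[i - 1L], w[i], 2L), ln = .init_ln(w[i]))
    blocks <- lapply(seq_len(cfg$stage_depths[i]), function(b)
      .init_ct_block(w[i], cfg$stage_reductions[i], cfg$mlp_ratio))
    stages[[i]] <- if (is.null(embed)) list(blocks = blocks)
                   else list(embed = embed, blocks = blocks)
  }
  list(stem = list(conv = .init_conv(cfg$in_channels, cfg$stem_width, 7L),
                   ln = .init_ln(cfg$stem_width)),
       stages = stages)
}

.check_patch <- function(x, in_channels, divisor = 16L) {
  if (length(dim(x)) != 4L)
    stop("expected a (channels, X, Y, Z) array, got ", length(dim(x)), " dims", call. = FALSE)
  if (dim(x)[1L] != in_channels)
    stop("expected ", in_channels, " input channels, got ", dim(x)[1L], call. = FALSE)
  sp <- dim(x)[-1L]
  bad <- which(sp %% divisor != 0L)
  if (length(bad))
    stop("spatial dim(s) ", paste(c("X", "Y", "Z")[bad], "=", sp[bad], collapse = ", "),
         " not divisible by ", divisor, call. = FALSE)
  .check_finite(x, "input patch")
  invisible(sp)
}

.stem_fwd <- function(p, x) {
  sp <- dim(x)[-1L]
  bad <- which(sp %% 2L != 0L | sp < 2L)
  if (length(bad))
    stop("stem requires even spatial dims >= 2; axis ",
         paste(c("X", "Y", "Z")[bad], collapse = ", "), " is not", call. = FALSE)
  .check_finite(x, "stem input")
  cv <- .conv_fwd(x, p$conv, stride = 2L, pad = 3L, name = "stem")
  tok <- .to_tokens(cv$y)
  ln <- .ln_fwd(tok, p$ln)
  ge <- .gelu_fwd(ln$y)
  list(tokens = ge$y, spatial = sp %/% 2L,
       cache = list(cv = cv$cache, ln = ln$cache, ge = ge$cache))
}

.stem_bwd <- function(p, cache, gtok) {
  g <- .gelu_bwd(cache$ge, gtok)
  lnb <- .ln_bwd(p$ln, cache$ln, g)
  sp_in <- dim(cache$cv$x)[-1L]
  cvb <- .conv_bwd(p$conv, cache$cv, .to_array(lnb$gx, sp_in %/% 2L))
  list(gx = cvb$gx, grads = list(conv = cvb$grads, ln = lnb$grads))
}

.embed_fwd <- function(p, tok, spatial) {
  bad <- which(spatial %% 2L != 0L)
  if (length(bad))
    stop("patch embedding requires even spatial dims; axis ",
         paste(c("X", "Y", "Z")[bad], collapse = ", "), " is odd", call. = FALSE)
  arr <- .to_array(tok, spatial)
  cv <- .conv_fwd(arr, p$conv, stride = 2L, pad = 0L, name = "patch_embed")
  t2 <- .to_tokens(cv$y)
  ln <- .ln_fwd(t2, p$ln)
  list(tokens = ln$y, spatial = spatial %/% 2L, cache = list(cv = cv$cache, ln = ln$cache))
}

.embed_bwd <- function(p, cache, gtok, spatial_out) {
  lnb <- .ln_bwd(p$ln, cache$ln, gtok)
  cvb <- .conv_bwd(p$conv, cache$cv, .to_array(lnb$gx, spatial_out))
  list(gtok = .to_tokens(cvb$gx), grads = list(conv = cvb$grads, ln = lnb$grads))
}

# Forward through the full encoder. Returns the feature pyramid (stage outputs
# at scales 2, 4, 8, 16 as (C, X, Y, Z) arrays with a `stage_scale` attribute)
# and, when `keep_cache`, everything needed for the backward pass.
.encoder_fwd <- function(params, x, cfg, keep_cache = FALSE) {
  .check_patch(x, cfg$in_channels)
  st <- .stem_fwd(params$stem, x)
  tok <- st$tokens; sp <- st$spatial
  pyramid <- vector("list", 4L)
  caches <- if (keep_cache) list(stem = st$cache, stages = vector("list", 4L))
  for (i in 1:4) {
    stg <- params$stages[[i]]
    ecache <- NULL
    if (i > 1L) {
      em <- .embed_fwd(stg$embed, tok, sp)
      tok <- em$tokens; sp <- em$spatial
      ecache <- em$cache
    }
    bcaches <- vector("list", length(stg$blocks))
    for (b in seq_along(stg$blocks)) {
      ct <- .ct_fwd(tok, sp, stg$blocks[[b]], cfg$stage_heads[i], cfg$stage_reductions[i])
      tok <- ct$y
      if (keep_cache) bcaches[[b]] <- ct$cache
    }
    pyramid[[i]] <- structure(.to_array(tok, sp), stage_scale = as.integer(2^i))
    if (keep_cache) caches$stages[[i]] <- list(embed = ecache, blocks = bcaches, spatial = sp)
  }
  list(pyramid = pyramid, cache = caches)
}

# gpyramid: list of 4 gradient arrays matching the pyramid levels.
.encoder_bwd <- function(params, cache, gpyramid, cfg) {
  gtok <- NULL
  grads <- list(stem = NULL, stages = vector("list", 4L))
  for (i in 4:1) {
    stg <- params$stages[[i]]
    scache <- cache$stages[[i]]
    g <- .to_tokens(gpyramid[[i]])
    if (!is.null(gtok)) g <- g + gtok
    bgrads <- vector("list", length(stg$blocks))
    for (b in rev(seq_along(stg$blocks))) {
      cb <- .ct_bwd(stg$blocks[[b]], scache$blocks[[b]], g)
      g <- cb$gx
      bgrads[[b]] <- cb$grads
    }
    if (i > 1L) {
      eb <- .embed_bwd(stg$embed, scache$embed, g, scache$spatial)
      gtok <- eb$gtok
      grads$stages[[i]] <- list(embed = eb$grads, blocks = bgrads)
    } else {
      grads$stages[[i]] <- list(blocks = bgrads)
      sb <- .stem_bwd(params$stem, cache$stem, g)
      grads$stem <- sb$grads
    }
  }
  grads
}
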