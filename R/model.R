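# Model configuration, S4 container, forward/backward assembly, checkpoints.

#' Model configuration
#'
#' Builds and validates the hyper-parameter set of the segmentation network.
#' The published configuration uses stage depths (2, 2, 2, 4), heads
#' (2, 4, 8, 16) and key/value reduction rates (8, 4, 2, 1); the stage widths
#' are the one free capacity parameter and the shipped defaults
#' (stem 60, widths 60/120/240/480) were calibrated once against the
#' 640-GFlops forward-pass budget at a 4-channel 128^3 input: over a grid of
#' stem widths in multiples of 4 with per-stage doubling, 60 minimises the
#' distance to the budget (665.7 GFlops, +4%). See [countFlops()].
#'
#' @param in_channels input image channels (4 for multi-modal brain MRI).
#' @param n_classes mutually exclusive output classes (background + 3 tissues).
#' @param stem_width channels produced by the 7x7x7 stride-2 stem; must equal
#'   `stage_widths[1]`.
#' @param stage_widths channel widths of the four encoder stages, strictly increasing.
#' @param stage_depths number of convolution-transformer blocks per stage.
#' @param stage_heads attention heads per stage; each must divide its stage width.
#' @param stage_reductions key/value reduction rate k per stage.
#' @param mlp_ratio hidden-layer expansion of the transformer MLP.
#' @param dw_kernel_length odd kernel length of the uni-directional convolutions
#'   in the direction-wise decoder blocks.
#' @param head_width channels of the final original-scale decoder block.
#' @param decoder_block `"dwconv"` for direction-wise blocks, `"residual"` for
#'   the plain residual-block ablation topology.
#' @param upsample_mode decoder upsampling; only `"convtranspose"` (kernel 2,
#'   stride 2) is implemented.
#' @param seed RNG seed for weight initialisation.
#' @return a validated config list of class `"tctnet_config"`.
#' @export
modelConfig <- function(in_channels = 4L, n_classes = 4L,
                        stem_width = 60L, stage_widths = c(60L, 120L, 240L, 480L),
                        stage_depths = c(2L, 2L, 2L, 4L),
                        stage_heads = c(2L, 4L, 8L, 16L),
                        stage_reductions = c(8L, 4L, 2L, 1L),
                        mlp_ratio = 4, dw_kernel_length = 7L,
                        head_width = max(stem_width %/% 2L, n_classes),
                        decoder_block = c("dwconv", "residual"),
                        upsample_mode = "convtranspose",
                        seed = 42L) {
  decoder_block <- match.arg(decoder_block)
  cfg <- list(in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
              stem_width = as.integer(stem_width), stage_widths = as.integer(stage_widths),
              stage_depths = as.integer(stage_depths), stage_heads = as.integer(stage_heads),
              stage_reductions = as.integer(stage_reductions), mlp_ratio = mlp_ratio,
              dw_kernel_length = as.integer(dw_kernel_length),
              head_width = as.integer(head_width), decoder_block = decoder_block,
              upsample_mode = upsample_mode, seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "tctnet_config"
  cfg
}

.validate_config <- function(cfg) {
  stopifnot(cfg$in_channels >= 1L, cfg$n_classes >= 2L,
            length(cfg$stage_widths) == 4L, length(cfg$stage_depths) == 4L,
            length(cfg$stage_heads) == 4L, length(cfg$stage_reductions) == 4L,
            all(cfg$stage_depths >= 1L), all(cfg$stage_reductions >= 1L),
            cfg$mlp_ratio > 0, cfg$dw_kernel_length %% 2L == 1L,
            cfg$head_width >= cfg$n_classes)
  if (cfg$stem_width != cfg$stage_widths[1L])
    stop("stem_width must equal stage_widths[1] (stem feeds stage 1 directly)", call. = FALSE)
  if (any(diff(cfg$stage_widths) <= 0L))
    stop("stage_widths must be strictly increasing", call. = FALSE)
  if (any(cfg$stage_widths %% cfg$stage_heads != 0L))
    stop("each stage width must be divisible by its head count", call. = FALSE)
  if (!identical(cfg$upsample_mode, "convtranspose"))
    stop("only upsample_mode = 'convtranspose' is implemented", call. = FALSE)
  invisible(TRUE)
}

#' Segmentation network container
#'
#' Holds the configuration and all learnable parameters of the hybrid
#' Transformer-CNN segmentation network.
#'
#' @slot config validated configuration list (see [modelConfig()]).
#' @slot params nested list of numeric parameter arrays.
#' @export
setClass("TCTNetModel", representation(config = "list", params = "list"),
         validity = function(object) {
           ok <- tryCatch({ .validate_config(object@config); TRUE },
                          error = function(e) conditionMessage(e))
           if (!isTRUE(ok)) return(ok)
           if (!all(c("encoder", "decoder") %in% names(object@params)))
             return("params must hold 'encoder' and 'decoder' trees")
           TRUE
         })

#' Construct an initialised segmentation network
#'
#' @param config configuration from [modelConfig()].
#' @return a [TCTNetModel-class] object with truncated-normal (sd 0.02)
#'   projection weights, unit norm gains and zero biases, drawn under
#'   `config$seed`.
#' @export
tctnet <- function(config = modelConfig()) {
  params <- .with_seed(config$seed, list(encoder = .init_encoder(config),
                                         decoder = .init_decoder(config)))
  new("TCTNetModel", config = unclass(config), params = params)
}

#' @describeIn TCTNetModel-class number of learnable parameters.
#' @param model a `TCTNetModel`.
#' @export
nParams <- function(model) .n_params(model@params)

setMethod("show", "TCTNetModel", function(object) {
  cfg <- object@config
  cat("TCTNetModel (hybrid Transformer-CNN 3D segmentation network)\n")
  cat(sprintf("  input channels: %d   classes: %d\n", cfg$in_channels, cfg$n_classes))
  cat(sprintf("  stage widths: %s (stem %d, head %d)\n",
              paste(cfg$stage_widths, collapse = "/"), cfg$stem_width, cfg$head_width))
  cat(sprintf("  depths %s | heads %s | K/V reductions %s\n",
              paste(cfg$stage_depths, collapse = "/"),
              paste(cfg$stage_heads, collapse = "/"),
              paste(cfg$stage_reductions, collapse = "/")))
  cat(sprintf("  decoder: %s blocks (kernel %d), %s upsampling\n",
              cfg$decoder_block, cfg$dw_kernel_length, cfg$upsample_mode))
  cat(sprintf("  parameters: %s\n", format(nParams(object), big.mark = ",")))
})

# ---- forward / backward -------------------------------------------------------

#' Encoder forward pass
#'
#' @param model a [TCTNetModel-class].
#' @param patch (in_channels, X, Y, Z) array; spatial dims divisible by 16.
#' @return feature pyramid: list of 4 (C, X, Y, Z) arrays at scales 2, 4, 8, 16
#'   (each carries a `stage_scale` attribute).
#' @export
encoderForward <- function(model, patch) {
  .encoder_fwd(model@params$encoder, patch, model@config)$pyramid
}

#' Decoder forward pass
#'
#' Fuses the feature pyramid back to the original scale (one direction-wise
#' block per decoder scale, including the original scale) and applies the
#' softmax head.
#'
#' @param model a [TCTNetModel-class].
#' @param pyramid feature pyramid from [encoderForward()].
#' @return (n_classes, X, Y, Z) per-voxel class probability array.
#' @export
decoderForward <- function(model, pyramid) {
  logits <- .decoder_fwd(model@params$decoder, pyramid, model@config)$logits
  structure(.softmax_channels(logits), stage_scale = 1L)
}

#' Full network forward pass
#'
#' @param model a [TCTNetModel-class].
#' @param patch (in_channels, X, Y, Z) array with spatial dims divisible by 16.
#' @param type `"prob"` for per-voxel class probabilities, `"logits"` for the
#'   pre-softmax head output.
#' @return (n_classes, X, Y, Z) array.
#' @export
tctnetForward <- function(model, patch, type = c("prob", "logits")) {
  type <- match.arg(type)
  r <- .model_fwd(model, patch, keep_cache = FALSE)
  if (type == "prob") .softmax_channels(r$logits) else r$logits
}

.model_fwd <- function(model, x, keep_cache = FALSE) {
  enc <- .encoder_fwd(model@params$encoder, x, model@config, keep_cache)
  dec <- .decoder_fwd(model@params$decoder, enc$pyramid, model@config, keep_cache)
  list(logits = dec$logits, n_blocks = dec$n_blocks,
       cache = if (keep_cache) list(enc = enc$cache, dec = dec$cache))
}

.model_bwd <- function(model, cache, glogits) {
  decb <- .decoder_bwd(model@params$decoder, cache$dec, glogits, model@config)
  encg <- .encoder_bwd(model@params$encoder, cache$enc, decb$gpyramid, model@config)
  list(encoder = encg, decoder = decb$grads)
}

# ---- checkpoints and parameter transfer ---------------------------------------

#' Save / load a model checkpoint
#'
#' @param model a [TCTNetModel-class].
#' @param path file path for the checkpoint.
#' @return `loadCheckpoint` returns the restored model.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  new("TCTNetModel", config = ck$config, params = ck$params)
}

#' Transfer compatible weights into a freshly initialised model
#'
#' Used for fine-tuning on a new dataset: every parameter whose shape matches
#' the source (in particular the four encoder stages, the "deep layers") is
#' copied; parameters whose shapes differ — the input stem when the channel
#' count changes, the head when the class count changes — keep their fresh
#' initialisation.
#'
#' @param source a trained [TCTNetModel-class] or checkpoint path.
#' @param config configuration of the new model.
#' @return list with `model` (the warm-started model), `n_loaded` and
#'   `n_reinit` (parameter counts copied vs. re-initialised).
#' @export
transferParameters <- function(source, config) {
  if (is.character(source)) source <- loadCheckpoint(source)
  if (!identical(source@config$stage_widths, as.integer(config$stage_widths)) ||
      !identical(source@config$stage_depths, as.integer(config$stage_depths)))
    stop("incompatible encoder width/depth schedule between source and target", call. = FALSE)
  target <- tctnet(config)
  n_loaded <- 0
  copy <- function(dst, src) {
    if (is.numeric(dst)) {
      if (is.numeric(src) && identical(dim(dst), dim(src)) && length(dst) == length(src)) {
        n_loaded <<- n_loaded + length(dst)
        return(src)
      }
      return(dst)
    }
    if (!is.list(src)) return(dst)
    keys <- if (is.null(names(dst))) seq_along(dst) else names(dst)
    for (k in keys) {
      s <- tryCatch(src[[k]], error = function(e) NULL)
      if (!is.null(s)) dst[[k]] <- copy(dst[[k]], s)
    }
    dst
  }
  target@params <- copy(target@params, source@params)
  list(model = target, n_loaded = n_loaded, n_reinit = nParams(target) - n_loaded)
}
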