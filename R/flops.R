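# Analytic forward-pass flop accounting.
#
# Convention: one multiply-add = 2 flops; normalisation, softmax and activation
# flops are ignored (the dominant-term convention of common profilers). The
# total under multiply-add = 1 is also reported so the printed number stays
# interpretable under either convention.

#' Forward-pass flop report
#'
#' @slot entries data.frame with one row per layer: `name`, `flops`.
#' @slot total_flops total flops (multiply-add = 2).
#' @slot total_gflops total in units of 1e9 flops.
#' @slot total_gflops_mac total GFlops under the multiply-add = 1 convention.
#' @slot convention human-readable statement of the counting convention.
#' @slot input_shape the (C, X, Y, Z) input the count refers to.
#' @export
setClass("FlopReport",
         representation(entries = "data.frame", total_flops = "numeric",
                        total_gflops = "numeric", total_gflops_mac = "numeric",
                        convention = "character", input_shape = "integer"),
         validity = function(object) {
           if (any(object@entries$flops < 0)) return("negative flop entry")
           if (abs(sum(object@entries$flops) - object@total_flops) > 1e-6 * max(1, object@total_flops))
             return("total does not equal the sum of entries")
           TRUE
         })

setMethod("show", "FlopReport", function(object) {
  cat(sprintf("FlopReport for input %s\n", paste(object@input_shape, collapse = "x")))
  cat(sprintf("  total: %.1f GFlops (%s)\n", object@total_gflops, object@convention))
  cat(sprintf("  total: %.1f GFlops under multiply-add = 1\n", object@total_gflops_mac))
  agg <- stats::aggregate(flops ~ name, data = object@entries, FUN = sum)
  agg <- agg[order(-agg$flops), ]
  agg$gflops <- round(agg$flops / 1e9, 2)
  agg$share <- sprintf("%.1f%%", 100 * agg$flops / object@total_flops)
  print(agg[, c("name", "gflops", "share")], row.names = FALSE)
})

#' @describeIn FlopReport-class total GFlops (multiply-add = 2).
#' @param report a `FlopReport`.
#' @export
flopTotal <- function(report) report@total_gflops

.conv_flops <- function(cin, cout, kvol, outvox, groups = 1) {
  2 * (cin / groups) * cout * kvol * outvox
}

#' Analytic flop count of one forward pass
#'
#' Walks the architecture implied by `config` and sums, per layer,
#' `2 * Cin/groups * Cout * kernel_volume * output_voxels` for convolutions and
#' `2 * L * L_kv * C` for each of the two attention matrix products, plus the
#' Q/K/V/output and MLP projections. The default published configuration on a
#' 4-channel 128^3 input lands on the 640-GFlops budget that calibrates the
#' otherwise free stage widths.
#'
#' @param config a [modelConfig()] configuration.
#' @param input_shape integer (C, X, Y, Z) input shape.
#' @return a [FlopReport-class].
#' @export
countFlops <- function(config, input_shape = c(4L, 128L, 128L, 128L)) {
  .validate_config(config)
  input_shape <- as.integer(input_shape)
  if (input_shape[1L] != config$in_channels)
    stop("input_shape channels do not match config$in_channels", call. = FALSE)
  sp0 <- input_shape[-1L]
  if (any(sp0 %% 16L != 0L)) stop("spatial dims must be divisible by 16", call. = FALSE)

  rows <- list()
  add <- function(name, flops) rows[[length(rows) + 1L]] <<- data.frame(name = name, flops = flops)

  w <- config$stage_widths
  add("stem", .conv_flops(config$in_channels, config$stem_width, 7^3, prod(sp0 %/% 2L)))

  for (i in 1:4) {
    sp <- sp0 %/% (2L^i)
    L <- prod(sp)
    C <- w[i]
    k <- config$stage_reductions[i]
    Lk <- if (k > 1L) L %/% k^3 else L
    kvk <- if (k > 1L) k^3 else 27
    if (i > 1L) add("patch_embed", .conv_flops(w[i - 1L], C, 8, L))
    hidden <- round(config$mlp_ratio * C)
    for (b in seq_len(config$stage_depths[i])) {
      add("kv_dwconv", 2 * .conv_flops(C, C, kvk, Lk, groups = C))
      add("linear", 2 * L * C * C)              # Wq
      add("linear", 2 * 2 * Lk * C * C)         # Wk, Wv
      add("attention", 2 * 2 * L * Lk * C)      # Q K' and A V
      add("linear", 2 * L * C * C)              # output merge
      add("linear", 2 * L * C * hidden + 2 * L * hidden * C)  # MLP
    }
  }

  dw_flops <- function(C, vox) {
    if (identical(config$decoder_block, "residual"))
      2 * .conv_flops(C, C, 27, vox)
    else
      6 * 3 * .conv_flops(C, C, config$dw_kernel_length, vox, groups = C) +
        .conv_flops(6 * C, C, 1, vox)
  }
  dec_name <- if (identical(config$decoder_block, "residual")) "res_conv" else "dw_block"
  for (j in 1:3) {
    cl <- w[5L - j]; cs <- w[4L - j]
    vox <- prod(sp0 %/% (2L^(4L - j)))
    add("fuse_up", .conv_flops(cl, cs, 8, vox))
    add("fuse_conv", .conv_flops(2 * cs, cs, 27, vox) + .conv_flops(cs, cs, 27, vox))
    add("fuse_short", .conv_flops(2 * cs, cs, 1, vox))
    add(dec_name, dw_flops(cs, vox))
  }
  add("final_up", .conv_flops(w[1L], config$head_width, 8, prod(sp0)))
  add(dec_name, dw_flops(config$head_width, prod(sp0)))
  add("head", .conv_flops(config$head_width, config$n_classes, 1, prod(sp0)))

  entries <- do.call(rbind, rows)
  total <- sum(entries$flops)
  new("FlopReport", entries = entries, total_flops = total,
      total_gflops = total / 1e9, total_gflops_mac = total / 2e9,
      convention = "one multiply-add = 2 flops; norm/activation/softmax ignored",
      input_shape = input_shape)
}

#' Instrumented flop count of an executed forward pass
#'
#' Runs a real forward pass through `model` on `patch` while every layer
#' wrapper records the flops of the operation it actually executed. Serves as
#' the run-time cross-check of the analytic [countFlops()].
#'
#' @param model a [TCTNetModel-class].
#' @param patch input array.
#' @return a [FlopReport-class] built from the executed operations.
#' @export
measureFlops <- function(model, patch) {
  .tally_start()
  on.exit(.tally$on <- FALSE)
  invisible(tctnetForward(model, patch, type = "logits"))
  entries <- .tally_stop()
  total <- sum(entries$flops)
  new("FlopReport", entries = entries, total_flops = total,
      total_gflops = total / 1e9, total_gflops_mac = total / 2e9,
      convention = "one multiply-add = 2 flops; norm/activation/softmax ignored",
      input_shape = as.integer(dim(patch)))
}
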