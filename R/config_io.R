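# YAML serialisation of the model / training / augmentation configuration.

#' Write a configuration to YAML
#'
#' @param config a [modelConfig()] or [trainConfig()] list (the augment block
#'   of a train config is nested under `augment`).
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Recognised keys: `in_channels`, `n_classes`, `stem_width`, `stage_widths`,
#' `stage_depths`, `stage_heads`, `stage_reductions`, `mlp_ratio`,
#' `dw_kernel_length`, `head_width`, `decoder_block`, `upsample_mode`, `seed`.
#' Missing keys fall back to the published defaults.
#'
#' @param path YAML file.
#' @return validated configuration via [modelConfig()].
#' @export
readModelConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(modelConfig))
  do.call(modelConfig, raw[intersect(names(raw), known)])
}

#' Read a training configuration from YAML
#'
#' @param path YAML file; an `augment` sub-block is passed to [augmentConfig()].
#' @return validated configuration via [trainConfig()].
#' @export
readTrainConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$augment) && is.list(raw$augment))
    raw$augment <- do.call(augmentConfig,
                           raw$augment[intersect(names(raw$augment), names(formals(augmentConfig)))])
  known <- names(formals(trainConfig))
  do.call(trainConfig, raw[intersect(names(raw), known)])
}
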