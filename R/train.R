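# Patch-based training: AdamW with cosine-annealed learning rate, a 1:1 mix of
# random and label-guided crops, gradient clipping, and best-by-validation
# checkpointing. Gradients come from the hand-derived backward passes.

#' Training configuration
#'
#' @param epochs training epochs (one crop per case per epoch); 300 is the
#'   full-scale default, desk-scale runs use far fewer.
#' @param batch_size crops per optimisation step (1 is the reference regime).
#' @param lr initial learning rate of AdamW (1e-4 reference default).
#' @param weight_decay AdamW decoupled weight decay.
#' @param schedule `"cosine"` annealing over epochs or `"constant"`.
#' @param patch_size training crop size per axis (divisible by 16).
#' @param crop_mix fraction of crops that are label-guided (0.5 = the 1:1 mix).
#' @param grad_clip global gradient-norm clip (guards the batch-size-1 regime).
#' @param val_fraction held-out fraction for the by-case validation split.
#' @param val_every validate (and refresh the best checkpoint) every this many epochs.
#' @param augment augmentation config from [augmentConfig()], or `NULL` to disable.
#' @param finetune_epochs epochs used by [runFinetune()] (200 reference default).
#' @param include_empty_classes see [softDiceCELoss()].
#' @param seed RNG seed for cropping, augmentation and the validation split.
#' @return validated configuration list.
#' @export
trainConfig <- function(epochs = 300L, batch_size = 1L, lr = 1e-4,
                        weight_decay = 1e-2, schedule = c("cosine", "constant"),
                        patch_size = c(128L, 128L, 128L), crop_mix = 0.5,
                        grad_clip = 1.0, val_fraction = 0.2, val_every = 5L,
                        augment = augmentConfig(), finetune_epochs = 200L,
                        include_empty_classes = FALSE, seed = 42L) {
  schedule <- match.arg(schedule)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, weight_decay >= 0,
            crop_mix >= 0, crop_mix <= 1, val_fraction >= 0, val_fraction < 1)
  patch_size <- as.integer(rep_len(patch_size, 3L))
  if (any(patch_size %% 16L != 0L)) stop("patch_size must be divisible by 16", call. = FALSE)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size), lr = lr,
       weight_decay = weight_decay, schedule = schedule, patch_size = patch_size,
       crop_mix = crop_mix, grad_clip = grad_clip, val_fraction = val_fraction,
       val_every = as.integer(val_every), augment = augment,
       finetune_epochs = as.integer(finetune_epochs),
       include_empty_classes = include_empty_classes, seed = as.integer(seed))
}

#' Cosine-annealed learning rate
#'
#' @param epoch 0-based epoch index.
#' @param total total epochs.
#' @param lr0 initial learning rate.
#' @return `lr0 * 0.5 * (1 + cos(pi * epoch / total))`.
#' @export
cosineLR <- function(epoch, total, lr0) lr0 * 0.5 * (1 + cos(pi * epoch / max(1L, total)))

# ---- AdamW over nested parameter trees ---------------------------------------

.adamw_init <- function(params) {
  list(m = .tree_map(function(x) x * 0, params),
       v = .tree_map(function(x) x * 0, params), t = 0L)
}

.adamw_step <- function(params, grads, state, lr, weight_decay = 1e-2,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- .tree_mapn(function(m, g) beta1 * m + (1 - beta1) * g, list(state$m, grads))
  state$v <- .tree_mapn(function(v, g) beta2 * v + (1 - beta2) * g * g, list(state$v, grads))
  params <- .tree_mapn(function(p, m, v) {
    p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
  }, list(params, state$m, state$v))
  list(params = params, state = state)
}

.clip_grads <- function(grads, max_norm) {
  gn <- .grad_global_norm(grads)
  if (is.finite(max_norm) && gn > max_norm)
    grads <- .tree_map(function(g) g * (max_norm / gn), grads)
  grads
}

# mean WT/TC/ET Dice of a model over cases (direct forward if the volume shape
# is network-admissible, otherwise sliding-window)
.validate_dice <- function(model, cases, roi = NULL) {
  scores <- vapply(cases, function(cs) {
    vshape <- dim(cs$image)[-1L]
    probs <- if (all(vshape %% 16L == 0L) && (is.null(roi) || all(vshape <= roi)))
      tctnetForward(model, cs$image)
    else slidingWindowInfer(cs$image, model, roi %||% pmin(vshape, 128L))
    pred <- labelsFromProbs(probs)
    gt <- regionsFromLabels(cs$labels)
    pr <- regionsFromLabels(pred)
    c(WT = diceScore(pr$WT, gt$WT), TC = diceScore(pr$TC, gt$TC), ET = diceScore(pr$ET, gt$ET))
  }, numeric(3L))
  rowMeans(scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hard labels from a probability map
#'
#' @param probs (n_classes, X, Y, Z) probability array.
#' @param classes label value of each channel (BraTS convention by default).
#' @return (X, Y, Z) integer label array.
#' @export
labelsFromProbs <- function(probs, classes = c(0L, 1L, 2L, 4L)) {
  C <- dim(probs)[1L]
  if (length(classes) != C) stop("classes must name every channel", call. = FALSE)
  idx <- apply(array(probs, dim = c(C, prod(dim(probs)[-1L]))), 2L, which.max)
  array(as.integer(classes[idx]), dim = dim(probs)[-1L])
}

#' Train a model in memory
#'
#' Each epoch draws one patch per case — alternating uniform-random and
#' label-guided crops in the configured mix — augments it, and takes one AdamW
#' step on the combined soft-dice + cross-entropy loss at the cosine-annealed
#' learning rate. Validation Dice is computed every `val_every` epochs and the
#' best-by-validation parameters are kept.
#'
#' @param model a [TCTNetModel-class].
#' @param cases list of cases, each `list(image = (C,X,Y,Z) array, labels = (X,Y,Z))`;
#'   images are percentile-normalised here if not already in `[0, 1]`.
#' @param cfg a [trainConfig()].
#' @param val_cases optional held-out cases for validation.
#' @return list with `model` (best by validation when available, else final),
#'   `final_model`, `history` (per-step loss and lr), `val_history`, `best_val`.
#' @export
trainModel <- function(model, cases, cfg = trainConfig(), val_cases = NULL) {
  if (length(cases) == 0L) stop("empty training set", call. = FALSE)
  norm_case <- function(cs) {
    if (max(cs$image) > 1 || min(cs$image) < 0) cs$image <- normaliseIntensity(cs$image)
    cs
  }
  cases <- lapply(cases, norm_case)
  if (!is.null(val_cases)) val_cases <- lapply(val_cases, norm_case)
  classes <- if (model@config$n_classes == 4L) c(0L, 1L, 2L, 4L) else
    seq_len(model@config$n_classes) - 1L

  params <- model@params
  state <- .adamw_init(params)
  history <- list(step = integer(), loss = numeric(), lr = numeric(), epoch = integer())
  val_history <- list(epoch = integer(), WT = numeric(), TC = numeric(), ET = numeric())
  best <- list(val = -Inf, params = params)
  step <- 0L

  set.seed(cfg$seed)
  n_draw <- 0L
  draw_pair <- function(cs) {
    guided <- (n_draw %% max(1L, round(1 / max(cfg$crop_mix, 1e-9)))) == 0L &&
      cfg$crop_mix > 0 && any(cs$labels > 0)
    n_draw <<- n_draw + 1L
    pair <- if (all(dim(cs$image)[-1L] == cfg$patch_size)) {
      list(image = cs$image, labels = cs$labels)
    } else if (guided) {
      labelGuidedCrop(cs$image, cs$labels, cfg$patch_size)
    } else {
      randomCrop(cs$image, cs$labels, cfg$patch_size)
    }
    if (!is.null(cfg$augment)) pair <- augmentPatch(pair, cfg$augment)
    pair
  }
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- if (cfg$schedule == "cosine") cosineLR(epoch, cfg$epochs, cfg$lr) else cfg$lr
    batches <- split(seq_along(cases), ceiling(seq_along(cases) / cfg$batch_size))
    for (bi in batches) {
      grads <- NULL
      loss <- 0
      model@params <- params
      for (ci in bi) {
        pair <- draw_pair(cases[[ci]])
        G <- if (model@config$n_classes == 4L) oneHotLabels(pair$labels) else
          oneHotLabels(pair$labels, classes)
        fwd <- .model_fwd(model, pair$image, keep_cache = TRUE)
        lg <- .dice_ce_grad(fwd$logits, G, include_empty_classes = cfg$include_empty_classes)
        if (!is.finite(lg$loss))
          stop("NaN/Inf loss at step ", step, " (epoch ", epoch, ", lr ", lr,
               "); inspect inputs and learning rate", call. = FALSE)
        g1 <- .model_bwd(model, fwd$cache, lg$grad)
        grads <- if (is.null(grads)) g1 else .tree_mapn(function(a, b) a + b, list(grads, g1))
        loss <- loss + lg$loss
      }
      if (length(bi) > 1L) grads <- .tree_map(function(g) g / length(bi), grads)
      loss <- loss / length(bi)
      grads <- .clip_grads(grads, cfg$grad_clip)
      upd <- .adamw_step(params, grads, state, lr, cfg$weight_decay)
      params <- upd$params
      state <- upd$state
      step <- step + 1L
      history$step <- c(history$step, step)
      history$loss <- c(history$loss, loss)
      history$lr <- c(history$lr, lr)
      history$epoch <- c(history$epoch, epoch)
    }
    if (!is.null(val_cases) && length(val_cases) &&
        (epoch %% cfg$val_every == 0L || epoch == cfg$epochs - 1L)) {
      model@params <- params
      vd <- .validate_dice(model, val_cases, roi = cfg$patch_size)
      val_history$epoch <- c(val_history$epoch, epoch)
      val_history$WT <- c(val_history$WT, vd[["WT"]])
      val_history$TC <- c(val_history$TC, vd[["TC"]])
      val_history$ET <- c(val_history$ET, vd[["ET"]])
      if (vd[["WT"]] > best$val) best <- list(val = vd[["WT"]], params = params)
    }
  }
  final <- model
  final@params <- params
  bestm <- model
  bestm@params <- if (is.finite(best$val)) best$params else params
  list(model = bestm, final_model = final,
       history = as.data.frame(history), val_history = as.data.frame(val_history),
       best_val = if (is.finite(best$val)) best$val else NA_real_)
}

#' File-based training run
#'
#' Loads a phantom dataset written by [generateDataset()], splits it 80/20 by
#' case under the fixed seed, trains, and writes the best checkpoint plus a
#' JSONL metrics log.
#'
#' @param data_dir dataset directory with `manifest.json`.
#' @param model_cfg a [modelConfig()].
#' @param train_cfg a [trainConfig()].
#' @param out_dir output directory for `checkpoint.rds` and `metrics.jsonl`.
#' @return the [trainModel()] result, invisibly.
#' @export
runTraining <- function(data_dir, model_cfg = modelConfig(), train_cfg = trainConfig(),
                        out_dir = file.path(data_dir, "run")) {
  man <- readManifest(data_dir)
  if (nrow(man$cases) == 0L) stop("empty dataset", call. = FALSE)
  cases <- lapply(seq_len(nrow(man$cases)), function(i) {
    list(image = loadVolume(file.path(data_dir, man$cases$image[i])),
         labels = loadLabels(file.path(data_dir, man$cases$label[i])))
  })
  n <- length(cases)
  n_val <- max(if (train_cfg$val_fraction > 0 && n > 1L) 1L else 0L,
               floor(train_cfg$val_fraction * n))
  idx_val <- if (n_val > 0L) .with_seed(train_cfg$seed, sample.int(n, n_val)) else integer()
  model <- tctnet(model_cfg)
  fit <- trainModel(model, cases[setdiff(seq_len(n), idx_val)], train_cfg,
                    val_cases = if (n_val > 0L) cases[idx_val])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  saveCheckpoint(fit$model, file.path(out_dir, "checkpoint.rds"))
  con <- file(file.path(out_dir, "metrics.jsonl"), "w")
  for (i in seq_len(nrow(fit$history)))
    writeLines(jsonlite::toJSON(as.list(fit$history[i, ]), auto_unbox = TRUE), con)
  close(con)
  invisible(fit)
}

#' Fine-tune from a checkpoint on a new dataset
#'
#' Loads every weight of matching shape from the source model (the four
#' encoder stages in particular); the input stem and segmentation head are
#' re-initialised when channel counts differ. Training then proceeds as in
#' [trainModel()] for `cfg$finetune_epochs` epochs.
#'
#' @param source a trained [TCTNetModel-class] or checkpoint path.
#' @param cases new-domain cases (see [trainModel()]).
#' @param model_cfg configuration of the fine-tuned model.
#' @param cfg a [trainConfig()]; `finetune_epochs` is used as the epoch budget.
#' @param val_cases optional validation cases.
#' @return the [trainModel()] result plus `n_loaded`/`n_reinit` parameter counts.
#' @export
runFinetune <- function(source, cases, model_cfg, cfg = trainConfig(), val_cases = NULL) {
  tr <- transferParameters(source, model_cfg)
  cfg$epochs <- cfg$finetune_epochs
  fit <- trainModel(tr$model, cases, cfg, val_cases)
  fit$n_loaded <- tr$n_loaded
  fit$n_reinit <- tr$n_reinit
  fit
}

#' Evaluate predictions against ground truth
#'
#' Computes WT/TC/ET Dice per case plus mean and standard deviation. Inputs
#' are either directories of NIfTI label maps (matched by file name) or lists
#' of label arrays.
#'
#' @param pred predicted label maps: directory or named list of (X, Y, Z) arrays.
#' @param gt ground-truth label maps in the same form.
#' @return data.frame with one row per case (`case`, `WT`, `TC`, `ET`) and
#'   attributes `mean` and `sd`.
#' @export
evaluateSegmentation <- function(pred, gt) {
  load_dir <- function(d) {
    files <- sort(list.files(d, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    setNames(lapply(files, loadLabels), sub("\\.nii(\\.gz)?$", "", basename(files)))
  }
  if (is.character(pred)) pred <- load_dir(pred)
  if (is.character(gt)) gt <- load_dir(gt)
  if (is.null(names(pred))) names(pred) <- sprintf("case_%03d", seq_along(pred))
  if (is.null(names(gt))) names(gt) <- sprintf("case_%03d", seq_along(gt))
  extra_p <- setdiff(names(pred), names(gt))
  extra_g <- setdiff(names(gt), names(pred))
  if (length(extra_p) || length(extra_g))
    stop("case lists differ; only in pred: [", paste(extra_p, collapse = ", "),
         "], only in gt: [", paste(extra_g, collapse = ", "), "]", call. = FALSE)
  rows <- lapply(names(gt), function(nm) {
    pr <- regionsFromLabels(pred[[nm]])
    gr <- regionsFromLabels(gt[[nm]])
    data.frame(case = nm, WT = diceScore(pr$WT, gr$WT),
               TC = diceScore(pr$TC, gr$TC), ET = diceScore(pr$ET, gr$ET))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- colMeans(out[, c("WT", "TC", "ET")])
  attr(out, "sd") <- apply(out[, c("WT", "TC", "ET")], 2L, sd)
  out
}
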