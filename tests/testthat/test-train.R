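# Training loop: optimisation sanity, schedule, determinism, fine-tuning,
# file-based runs, evaluation reports.

small_train_cases <- function(n, seed0, shape = c(16L, 16L, 16L), radius = c(3, 4)) {
  lapply(seq_len(n), function(i)
    generatePhantom(phantomSpec(shape = shape, lesion_radius_range = radius,
                                seed = seed0 + i)))
}

test_that("50 optimisation steps reduce the training loss on one phantom", {
  ph <- small_train_cases(1L, 80L)[[1]]
  m <- tctnet(tiny_config(in_channels = 4L))
  cfg <- trainConfig(epochs = 50L, lr = 1e-3, schedule = "constant",
                     patch_size = 16L, augment = NULL, val_every = 1000L, seed = 1L)
  fit <- trainModel(m, list(ph), cfg)
  expect_lt(tail(fit$history$loss, 1L), fit$history$loss[1L])
  expect_lt(mean(tail(fit$history$loss, 5L)), mean(head(fit$history$loss, 5L)))
})

test_that("cosine schedule starts at the configured rate and anneals to near zero", {
  expect_equal(cosineLR(0L, 300L, 1e-4), 1e-4)
  expect_lt(cosineLR(299L, 300L, 1e-4), 1e-4)
  expect_gt(cosineLR(150L, 300L, 1e-4), 0)
  cfg <- trainConfig(epochs = 4L, lr = 1e-4, patch_size = 16L, augment = NULL,
                     val_every = 1000L, seed = 2L)
  ph <- small_train_cases(1L, 81L)[[1]]
  fit <- trainModel(tctnet(tiny_config(in_channels = 4L)), list(ph), cfg)
  lrs <- unique(fit$history$lr)
  expect_equal(lrs[1L], 1e-4)
  expect_lt(tail(lrs, 1L), lrs[1L])
})

test_that("training is reproducible under a fixed seed", {
  cases <- small_train_cases(2L, 82L)
  cfg <- trainConfig(epochs = 2L, lr = 1e-3, patch_size = 16L, val_every = 1000L, seed = 3L)
  f1 <- trainModel(tctnet(tiny_config(in_channels = 4L)), cases, cfg)
  f2 <- trainModel(tctnet(tiny_config(in_channels = 4L)), cases, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$final_model@params, f2$final_model@params)
})

test_that("gradient accumulation over a batch matches the configured batch size", {
  cases <- small_train_cases(4L, 83L)
  cfg <- trainConfig(epochs = 1L, batch_size = 2L, lr = 1e-3, patch_size = 16L,
                     augment = NULL, val_every = 1000L, seed = 4L)
  fit <- trainModel(tctnet(tiny_config(in_channels = 4L)), cases, cfg)
  expect_identical(nrow(fit$history), 2L)   # 4 cases / batch of 2
})

test_that("file-based training writes a checkpoint and a metrics log", {
  td <- withr::local_tempdir()
  spec <- phantomSpec(shape = c(16L, 16L, 16L), lesion_radius_range = c(3, 4), seed = 84L)
  generateDataset(3L, spec, td)
  out <- file.path(td, "run")
  fit <- runTraining(td, tiny_config(in_channels = 4L),
                     trainConfig(epochs = 2L, lr = 1e-3, patch_size = 16L,
                                 val_every = 1L, seed = 5L), out)
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  lines <- readLines(file.path(out, "metrics.jsonl"))
  expect_identical(length(lines), nrow(fit$history))
  expect_true(all(c("WT", "TC", "ET") %in% names(fit$val_history)))
  m <- loadCheckpoint(file.path(out, "checkpoint.rds"))
  expect_s4_class(m, "TCTNetModel")
  expect_error(runTraining(file.path(td, "nowhere")), "manifest")
})

test_that("fine-tuning warm-starts near the pre-training loss and transfers across channels", {
  cases <- small_train_cases(2L, 85L)
  cfg <- trainConfig(epochs = 15L, lr = 1e-3, schedule = "constant", patch_size = 16L,
                     augment = NULL, val_every = 1000L, seed = 6L, finetune_epochs = 2L)
  pre <- trainModel(tctnet(tiny_config(in_channels = 4L)), cases, cfg)
  pre_loss <- mean(tail(pre$history$loss, 2L))

  ft <- runFinetune(pre$final_model, cases, tiny_config(in_channels = 4L, seed = 9L), cfg)
  expect_equal(ft$n_reinit, 0)
  expect_lt(abs(ft$history$loss[1L] - pre_loss), 0.25)
  expect_lt(ft$history$loss[1L], pre$history$loss[1L])  # warm start beats cold start

  # new single-channel domain: stem is re-initialised, encoder stages carried over
  cases1 <- lapply(cases, function(cs) { cs$image <- cs$image[1, , , , drop = FALSE]; cs })
  ft1 <- runFinetune(pre$final_model, cases1, tiny_config(in_channels = 1L, seed = 9L), cfg)
  expect_gt(ft1$n_reinit, 0)
  expect_equal(ft1$n_reinit,
               length(tctnet(tiny_config(in_channels = 1L))@params$encoder$stem$conv$w))
})

test_that("fine-tuning beats from-scratch training at an equal step budget", {
  cases_a <- small_train_cases(3L, 86L)
  cfg_pre <- trainConfig(epochs = 25L, lr = 1e-3, schedule = "constant", patch_size = 16L,
                         augment = NULL, val_every = 1000L, seed = 7L)
  pre <- trainModel(tctnet(tiny_config(in_channels = 4L)), cases_a, cfg_pre)

  deltas <- vapply(1:3, function(s) {
    cases_b <- small_train_cases(2L, 90L + 10L * s)
    cfg_ft <- trainConfig(epochs = 5L, lr = 1e-3, schedule = "constant", patch_size = 16L,
                          augment = NULL, val_every = 1000L, seed = s, finetune_epochs = 5L)
    ft <- runFinetune(pre$final_model, cases_b, tiny_config(in_channels = 4L, seed = s), cfg_ft)
    scratch <- trainModel(tctnet(tiny_config(in_channels = 4L, seed = s)), cases_b, cfg_ft)
    mean(tail(scratch$history$loss, 3L)) - mean(tail(ft$history$loss, 3L))
  }, 0)
  expect_gt(mean(deltas), 0)
})

test_that("evaluation reports per-case and aggregate Dice with case matching", {
  ph <- small_train_cases(2L, 87L)
  gt <- lapply(ph, `[[`, "labels")
  ev <- evaluateSegmentation(gt, gt)
  expect_true(all(ev$WT == 1 & ev$TC == 1 & ev$ET == 1))
  expect_equal(unname(attr(ev, "mean")), c(1, 1, 1))

  none <- lapply(gt, function(l) array(0L, dim(l)))
  ev0 <- evaluateSegmentation(none, gt)
  expect_true(all(ev0$WT == 0))

  # half-eroded prediction: Dice matches direct counting
  pred <- gt
  keep <- which(pred[[1]] > 0)
  drop <- keep[seq_len(length(keep) %/% 2L)]
  pred[[1]][drop] <- 0L
  ev2 <- evaluateSegmentation(pred, gt)
  a <- sum(pred[[1]] > 0); b <- sum(gt[[1]] > 0)
  expect_equal(ev2$WT[1L], 2 * a / (a + b))

  names(pred) <- c("x", "y")
  expect_error(evaluateSegmentation(pred, gt), "only in pred")
})

test_that("labels derive from probabilities by per-voxel argmax onto BraTS values", {
  p <- array(0, c(4, 2, 1, 1))
  p[, 1, 1, 1] <- c(0.1, 0.2, 0.6, 0.1)
  p[, 2, 1, 1] <- c(0.1, 0.1, 0.2, 0.6)
  lab <- labelsFromProbs(p)
  expect_identical(as.vector(lab), c(2L, 4L))
  expect_error(labelsFromProbs(p, classes = c(0L, 1L)), "every channel")
})
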