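# Combined soft-dice + cross-entropy loss, Dice similarity, and the derivation
# of the nested tumour regions (WT/TC/ET) from exclusive labels.

#' Combined soft dice and cross-entropy loss
#'
#' For per-voxel class probabilities P and targets G over I voxels and C
#' classes the loss is
#' \deqn{L = -\frac{1}{I}\sum_i \sum_c G_{ic} \log P_{ic} \;+\; 1 -
#'       \frac{2}{C}\sum_c \frac{\sum_i G_{ic} P_{ic}}
#'       {\sum_i G_{ic}^2 + \sum_i P_{ic}^2 + \epsilon},}
#' i.e. voxel-mean cross-entropy plus one minus the mean soft dice fraction
#' (each class's fraction approaches 1/2 at a perfect prediction, so L -> 0).
#' The log is clamped at P >= 1e-7.
#'
#' @param P (C, ...) array or C x I matrix of probabilities on the per-voxel simplex.
#' @param G same shape as `P`; one-hot targets for exclusive training, but any
#'   grid in `[0,1]` is accepted (e.g. overlapping region channels).
#' @param eps dice smoothing constant added to each class denominator.
#' @param include_empty_classes if `TRUE`, classes absent from `G` contribute a
#'   zero dice fraction but still count in the `2/C` normalisation (the literal
#'   reading); if `FALSE` (default) absent classes are dropped from both the
#'   sum and the normalisation.
#' @return scalar loss, always >= 0 up to the epsilon smoothing.
#' @export
softDiceCELoss <- function(P, G, eps = 1e-5, include_empty_classes = FALSE) {
  if (!identical(dim(P), dim(G)) || length(P) != length(G))
    stop("P and G shapes differ", call. = FALSE)
  if (min(P) < -1e-12 || max(P) > 1 + 1e-12)
    stop("P must lie in [0, 1]", call. = FALSE)
  C <- if (is.null(dim(P))) stop("P needs a class dimension", call. = FALSE) else dim(P)[1L]
  Pm <- matrix(P, nrow = C)
  Gm <- matrix(G, nrow = C)
  I <- ncol(Pm)
  ce <- -sum(Gm * log(pmax(Pm, 1e-7))) / I
  num <- rowSums(Gm * Pm)
  den <- rowSums(Gm * Gm) + rowSums(Pm * Pm) + eps
  frac <- num / den
  present <- rowSums(Gm) > 0
  if (include_empty_classes) dice <- (2 / C) * sum(frac)
  else if (any(present)) dice <- (2 / sum(present)) * sum(frac[present])
  else dice <- 0
  ce + 1 - dice
}

# loss + gradient w.r.t. the pre-softmax logits, used by the training loop
.dice_ce_grad <- function(logits, G, eps = 1e-5, include_empty_classes = FALSE) {
  C <- dim(logits)[1L]
  dims <- dim(logits)
  Zm <- matrix(logits, nrow = C)
  Gm <- matrix(G, nrow = C)
  I <- ncol(Zm)
  m <- apply(Zm, 2L, max)
  e <- exp(sweep(Zm, 2L, m, "-"))
  Pm <- sweep(e, 2L, colSums(e), "/")
  Pc <- pmax(Pm, 1e-7)
  ce <- -sum(Gm * log(Pc)) / I
  num <- rowSums(Gm * Pm)
  den <- rowSums(Gm * Gm) + rowSums(Pm * Pm) + eps
  frac <- num / den
  present <- rowSums(Gm) > 0
  norm <- if (include_empty_classes) 2 / C else if (any(present)) 2 / sum(present) else 0
  counted <- if (include_empty_classes) rep(TRUE, C) else present
  loss <- ce + 1 - norm * sum(frac[counted])
  # dL/dP
  gP <- -(Gm / Pc) / I
  sel <- which(counted)
  gP[sel, ] <- gP[sel, , drop = FALSE] -
    norm * (Gm[sel, , drop = FALSE] * (1 / den[sel]) -
            Pm[sel, , drop = FALSE] * (2 * num[sel] / den[sel]^2))
  # chain through per-voxel softmax
  dot <- colSums(gP * Pm)
  gz <- Pm * sweep(gP, 2L, dot, "-")
  list(loss = loss, grad = array(gz, dim = dims), P = array(Pm, dim = dims))
}

#' Dice similarity coefficient between two masks
#'
#' `2 |A and B| / (|A| + |B|)`; returns 1 when both masks are empty
#' (the empty-region convention used when scoring cases without a tissue).
#'
#' @param pred_mask,gt_mask logical arrays of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
diceScore <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("mask shapes differ", call. = FALSE)
  a <- sum(pred_mask); b <- sum(gt_mask)
  if (a + b == 0) return(1)
  2 * sum(pred_mask & gt_mask) / (a + b)
}

#' Derive nested tumour regions from exclusive labels
#'
#' Converts a BraTS-convention label map (0 background, 1 necrotic /
#' non-enhancing core, 2 peritumoral edema, 4 enhancing tumour) into the three
#' nested evaluation regions: whole tumour WT = \{1,2,4\}, tumour core
#' TC = \{1,4\}, enhancing tumour ET = \{4\}, so ET is a subset of TC is a
#' subset of WT by construction.
#'
#' @param labels integer 3D array with values in \{0, 1, 2, 4\}.
#' @return list of logical arrays `WT`, `TC`, `ET`.
#' @export
regionsFromLabels <- function(labels) {
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, c(0L, 1L, 2L, 4L))
  if (length(bad))
    stop("unknown label value(s): ", paste(sort(bad), collapse = ", "),
         " (expected 0, 1, 2, 4)", call. = FALSE)
  list(WT = array(labels %in% c(1L, 2L, 4L), dim = dim(labels)),
       TC = array(labels %in% c(1L, 4L), dim = dim(labels)),
       ET = array(labels == 4L, dim = dim(labels)))
}

#' One-hot encoding of an exclusive label map
#'
#' @param labels integer 3D array with values in \{0, 1, 2, 4\}.
#' @param classes label values mapped to channels, in channel order.
#' @return (length(classes), X, Y, Z) 0/1 array, one-hot at every voxel.
#' @export
oneHotLabels <- function(labels, classes = c(0L, 1L, 2L, 4L)) {
  d <- dim(labels)
  out <- array(0, dim = c(length(classes), d))
  for (i in seq_along(classes)) out[i, , , ] <- as.numeric(labels == classes[i])
  out
}

#' Overlapping region channels of a label map
#'
#' Target channels for the literal 3-channel reading of the network output
#' (WT/TC/ET trained jointly under one softmax); provided for completeness,
#' exclusive labels are the default training mode.
#'
#' @param labels integer 3D array with values in \{0, 1, 2, 4\}.
#' @return (3, X, Y, Z) 0/1 array with channels WT, TC, ET (not one-hot).
#' @export
regionTargetChannels <- function(labels) {
  r <- regionsFromLabels(labels)
  d <- dim(labels)
  out <- array(0, dim = c(3L, d))
  out[1, , , ] <- as.numeric(r$WT)
  out[2, , , ] <- as.numeric(r$TC)
  out[3, , , ] <- as.numeric(r$ET)
  out
}
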