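# Synthetic BraTS-like phantoms: multi-channel contrast, nested lesion regions
# (enhancing core inside tumour core inside whole tumour), dominant background.
# Lesions are axis-aligned ellipsoids so region volumes stay analytically
# checkable.

#' Phantom specification
#'
#' @param shape (X, Y, Z) volume shape.
#' @param n_channels image channels (4 emulates the four MRI modalities).
#' @param n_lesions number of ellipsoidal lesions.
#' @param lesion_radius_range per-axis radius range in voxels.
#' @param nesting_fractions `(f_TC, f_ET)`: the tumour-core and enhancing-core
#'   ellipsoids have radii `f_TC * r` and `f_ET * r` of the whole-tumour radii,
#'   with `f_ET <= f_TC <= 1`.
#' @param noise_sd standard deviation of the additive Gaussian intensity noise.
#' @param seed RNG seed; the phantom is fully determined by the spec.
#' @return validated specification list.
#' @export
phantomSpec <- function(shape = c(128L, 128L, 128L), n_channels = 4L,
                        n_lesions = 1L, lesion_radius_range = c(9, 11),
                        nesting_fractions = c(0.6, 0.35),
                        noise_sd = 0.03, seed = 1L) {
  spec <- list(shape = as.integer(rep_len(shape, 3L)), n_channels = as.integer(n_channels),
               n_lesions = as.integer(n_lesions),
               lesion_radius_range = as.numeric(lesion_radius_range),
               nesting_fractions = as.numeric(nesting_fractions),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  stopifnot(all(spec$shape >= 8L), spec$n_channels >= 1L, spec$n_lesions >= 0L,
            spec$lesion_radius_range[1L] >= 1,
            spec$lesion_radius_range[2L] >= spec$lesion_radius_range[1L],
            spec$noise_sd >= 0)
  f <- spec$nesting_fractions
  if (!(f[2L] <= f[1L] && f[1L] <= 1 && f[2L] > 0))
    stop("nesting fractions must satisfy 0 < f_ET <= f_TC <= 1", call. = FALSE)
  spec
}

# Per-channel tissue contrasts relative to healthy brain, emulating the four
# BraTS modalities (FLAIR / T1w / T1gd / T2w): edema bright on FLAIR and T2,
# necrosis dark on T1, enhancing core bright on T1gd. Contrasts sit inside the
# healthy-tissue intensity spread (the anatomical texture in generatePhantom)
# so the p5/p95 normalisation preserves them, and a base offset of 0.2 per
# channel keeps channel means distinguishable well above the noise floor.
# Rows = channels (patterns recycled past 4), columns = (brain, edema,
# necrotic, enhancing).
.tissue_means <- function(n_channels) {
  patterns <- rbind(c(0, +0.13, -0.06, +0.06),   # FLAIR-like
                    c(0, -0.05, -0.12, -0.03),   # T1w-like
                    c(0, -0.03, -0.09, +0.13),   # T1gd-like
                    c(0, +0.11, +0.06, +0.03))   # T2w-like
  t(vapply(seq_len(n_channels), function(ch) {
    0.5 + 0.2 * (ch - 1L) + patterns[((ch - 1L) %% 4L) + 1L, ]
  }, numeric(4L)))
}

#' Generate a synthetic phantom
#'
#' Draws a large healthy-tissue ellipsoid (nonzero intensity, label 0) on a
#' zero background (the skull-stripped analogue), then places `n_lesions`
#' axis-aligned ellipsoidal lesions fully inside the volume: an edema shell
#' (label 2) with a concentric necrotic/non-enhancing ring (label 1) and an
#' enhancing core (label 4), following the BraTS label convention. Each channel
#' gets a distinct per-tissue mean plus Gaussian noise.
#'
#' @param spec a [phantomSpec()].
#' @return list with `image` (C, X, Y, Z array) and `labels` (X, Y, Z integer
#'   array with values in \{0, 1, 2, 4\}); deterministic given `spec$seed`.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  .with_seed(spec$seed, {
    d <- spec$shape
    cx <- (d + 1) / 2
    gx <- seq_len(d[1L]); gy <- seq_len(d[2L]); gz <- seq_len(d[3L])
    # healthy-tissue ellipsoid filling most of the volume; kept large so the
    # lesion stays a small fraction of the foreground and the p5/p95
    # normalisation percentiles remain stable across cases
    br <- 0.48 * d
    u2 <- outer(outer(((gx - cx[1L]) / br[1L])^2, ((gy - cx[2L]) / br[2L])^2, "+"),
                ((gz - cx[3L]) / br[3L])^2, "+")
    brain <- u2 <= 1
    labels <- array(0L, dim = d)
    f <- spec$nesting_fractions
    rng <- spec$lesion_radius_range
    if (rng[2L] + 2 > min(d) / 2 - 1)
      stop("lesion radius ", rng[2L], " cannot fit inside shape ",
           paste(d, collapse = "x"), call. = FALSE)
    for (l in seq_len(spec$n_lesions)) {
      r <- runif(3L, rng[1L], rng[2L])
      margin <- ceiling(r) + 2
      ctr <- vapply(1:3, function(a) runif(1L, 1 + margin[a], d[a] - margin[a]), 0)
      v2 <- outer(outer(((gx - ctr[1L]) / r[1L])^2, ((gy - ctr[2L]) / r[2L])^2, "+"),
                  ((gz - ctr[3L]) / r[3L])^2, "+")
      labels[v2 <= 1] <- 2L                 # edema shell
      labels[v2 <= f[1L]^2] <- 1L           # necrotic / non-enhancing ring
      labels[v2 <= f[2L]^2] <- 4L           # enhancing core
    }
    means <- .tissue_means(spec$n_channels)
    tissue_idx <- array(0L, dim = d)        # 0 bg, 1 brain, 2 edema, 3 necro, 4 enh
    tissue_idx[brain] <- 1L
    tissue_idx[labels == 2L] <- 2L
    tissue_idx[labels == 1L] <- 3L
    tissue_idx[labels == 4L] <- 4L
    # anatomical texture: per-voxel intensity variation shared by all channels
    # (the same anatomy is imaged in every modality), wide enough that the
    # p5/p95 normalisation band spans the tissue contrasts and its percentiles
    # stay stable from case to case
    bias <- array(runif(prod(d), -0.35, 0.35), dim = d)
    fg <- tissue_idx > 0L
    img <- array(0, dim = c(spec$n_channels, d))
    for (ch in seq_len(spec$n_channels)) {
      v <- array(0, dim = d)
      for (t in 1:4) v[tissue_idx == t] <- means[ch, t]
      noise <- array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
      v[fg] <- pmax(v[fg] + bias[fg] + noise[fg], 1e-3)
      img[ch, , , ] <- v
    }
    list(image = img, labels = labels)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` image/label NIfTI pairs plus a JSON manifest holding the
#' per-case seeds and lesion statistics, so any case can be regenerated
#' bit-identically from its manifest entry.
#'
#' @param n_cases number of cases.
#' @param spec base [phantomSpec()]; case `i` uses seed `spec$seed + i - 1`.
#' @param out_dir writable output directory (created if missing).
#' @return the manifest as a data.frame, invisibly; written to
#'   `manifest.json` alongside the NIfTI files.
#' @export
generateDataset <- function(n_cases, spec = phantomSpec(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cspec <- spec
    cspec$seed <- spec$seed + i - 1L
    ph <- generatePhantom(cspec)
    img_path <- file.path(out_dir, sprintf("case_%03d_image.nii.gz", i))
    lbl_path <- file.path(out_dir, sprintf("case_%03d_label.nii.gz", i))
    savePrediction(img_path, ph$image)
    savePrediction(lbl_path, ph$labels)
    rows[[i]] <- data.frame(case = sprintf("case_%03d", i), seed = cspec$seed,
                            image = basename(img_path), label = basename(lbl_path),
                            wt_ratio = tumourRatio(ph$labels, "WT"),
                            tc_ratio = tumourRatio(ph$labels, "TC"),
                            et_ratio = tumourRatio(ph$labels, "ET"))
  }
  manifest <- do.call(rbind, rows)
  spec_out <- spec
  spec_out$shape <- as.list(spec_out$shape)
  jsonlite::write_json(list(spec = spec_out, cases = manifest),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list with `spec` and `cases` (data.frame).
#' @export
readManifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
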