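# Intensity normalisation, cropping, augmentation, NIfTI round trips.

test_that("percentile normalisation matches a quantile oracle and clips to [0, 1]", {
  set.seed(40)
  vol <- array(0, c(1, 10, 10, 10))
  fg_idx <- sample(1000, 400)
  fg_vals <- runif(400, 10, 200)
  vol[1, , , ][fg_idx] <- fg_vals
  out <- normaliseIntensity(vol)
  q <- quantile(fg_vals, c(0.05, 0.95), names = FALSE)
  expected <- pmin(pmax((fg_vals - q[1]) / (q[2] - q[1]), 0), 1)
  expect_lt(max(abs(out[1, , , ][fg_idx] - expected)), 1e-12)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  # values above p95 clip to exactly 1
  expect_equal(out[1, , , ][fg_idx][which.max(fg_vals)], 1)
})

test_that("normalisation is a no-op on input already spanning [0, 1] at its percentiles", {
  set.seed(41)
  vol <- array(0, c(1, 12, 12, 12))
  vals <- c(rep(1e-12, 120), runif(1200, 0.2, 0.8), rep(1, 120))
  vol[1, , , ][seq_along(vals)] <- vals
  out <- normaliseIntensity(vol)
  expect_lt(max(abs(out - vol)), 1e-9)
})

test_that("normalisation rejects all-zero and degenerate channels", {
  expect_error(normaliseIntensity(array(0, c(1, 4, 4, 4))), "all zero")
  vol <- array(0, c(1, 4, 4, 4)); vol[1, , , 1] <- 5
  expect_error(normaliseIntensity(vol), "degenerate")
})

test_that("random crop covers all valid origins uniformly and is seed-deterministic", {
  set.seed(42)
  vol <- array(rnorm(1 * 16 * 8 * 8), c(1, 16, 8, 8))
  lab <- array(0L, c(16, 8, 8))

  pr <- randomCrop(vol, lab, c(16L, 8L, 8L))
  expect_identical(pr$origin, c(0L, 0L, 0L))
  expect_identical(pr$image, vol)

  set.seed(1); o1 <- randomCrop(vol, lab, 8L)$origin
  set.seed(1); o2 <- randomCrop(vol, lab, 8L)$origin
  expect_identical(o1, o2)

  # axis 1 is 2x the crop: origins 0..8, uniform by chi-square at alpha 0.01
  set.seed(43)
  draws <- replicate(10000, randomCrop(vol, lab, 8L)$origin[1])
  tab <- table(factor(draws, levels = 0:8))
  expect_gt(chisq.test(tab)$p.value, 0.01)

  expect_error(randomCrop(vol, lab, 32L), "pad")
})

test_that("label-guided crop centres on foreground and always contains it", {
  vol <- array(rnorm(1 * 16^3), c(1, 16, 16, 16))
  lab <- array(0L, c(16, 16, 16))
  lab[8, 8, 8] <- 2L
  set.seed(44)
  pr <- labelGuidedCrop(vol, lab, 8L)
  expect_identical(pr$origin, c(3L, 3L, 3L))   # centred on the single voxel
  expect_gte(sum(pr$labels > 0), 1L)

  # foreground near the boundary: origin clips, foreground retained
  lab2 <- array(0L, c(16, 16, 16)); lab2[1, 16, 2] <- 4L
  for (i in 1:5) {
    pr2 <- labelGuidedCrop(vol, lab2, 8L)
    expect_gte(sum(pr2$labels > 0), 1L)
  }
  expect_error(labelGuidedCrop(vol, array(0L, c(16, 16, 16)), 8L), "foreground")
})

test_that("guided crops enrich tumour content over random crops on a small lesion", {
  ph <- small_phantom(seed = 45L, shape = c(48L, 48L, 48L), radius = c(5, 6))
  set.seed(46)
  r_rand <- mean(replicate(10, tumourRatio(randomCrop(ph$image, ph$labels, 16L)$labels, "WT")))
  r_guid <- mean(replicate(10, tumourRatio(labelGuidedCrop(ph$image, ph$labels, 16L)$labels, "WT")))
  expect_gt(r_guid, r_rand)
})

test_that("augmentation at zero probability is the identity and flips are involutions", {
  ph <- small_phantom(seed = 47L, shape = c(16L, 16L, 16L), radius = c(3, 4))
  pair <- list(image = ph$image, labels = ph$labels)
  cfg0 <- augmentConfig(p_flip = 0, p_rot90 = 0, p_scale = 0, p_shift = 0, p_noise = 0)
  expect_identical(augmentPatch(pair, cfg0), pair)
  for (ax in 1:3)
    expect_identical(flipPatch(flipPatch(pair, ax), ax), pair)
  expect_error(augmentConfig(p_flip = 1.5), "\\[0, 1\\]")
})

test_that("spatial augmentations preserve label counts and commute with region derivation", {
  ph <- small_phantom(seed = 48L, shape = c(16L, 16L, 16L), radius = c(3, 4))
  pair <- list(image = ph$image, labels = ph$labels)
  n_fg <- sum(pair$labels > 0)
  for (op in list(function(p) flipPatch(p, 2L),
                  function(p) rotatePatch90(p, c(1L, 3L), 1L),
                  function(p) rotatePatch90(p, c(2L, 3L), 3L))) {
    out <- op(pair)
    expect_identical(sum(out$labels > 0), n_fg)
    # region masks of transformed labels equal transformed region masks
    r_after <- regionsFromLabels(out$labels)
    r_before <- regionsFromLabels(pair$labels)
    moved <- op(list(image = pair$image,
                     labels = array(as.integer(r_before$WT) * 2L, dim(pair$labels))))
    expect_identical(r_after$WT, regionsFromLabels(moved$labels)$WT)
  }
})

test_that("intensity augmentations leave labels untouched", {
  ph <- small_phantom(seed = 49L, shape = c(16L, 16L, 16L), radius = c(3, 4))
  pair <- list(image = ph$image, labels = ph$labels)
  cfg <- augmentConfig(p_flip = 0, p_rot90 = 0, p_scale = 1, p_shift = 1, p_noise = 1)
  set.seed(50)
  out <- augmentPatch(pair, cfg)
  expect_identical(out$labels, pair$labels)
  expect_gt(max(abs(out$image - pair$image)), 0)
})

test_that("tumour ratio counts region voxels over volume voxels", {
  lab <- array(0L, c(2, 2, 2))
  expect_equal(tumourRatio(lab, "WT"), 0)
  lab[1:2] <- 2L
  expect_equal(tumourRatio(lab, "WT"), 0.25)
  expect_equal(tumourRatio(lab, "TC"), 0)
  expect_equal(tumourRatio(array(4L, c(2, 2, 2)), "ET"), 1)
})

test_that("NIfTI round trip preserves shape, spacing and values", {
  ph <- small_phantom(seed = 51L, shape = c(16L, 16L, 16L), radius = c(3, 4))
  td <- withr::local_tempdir()
  img_path <- file.path(td, "img.nii.gz")
  lbl_path <- file.path(td, "lbl.nii.gz")
  savePrediction(img_path, ph$image)
  savePrediction(lbl_path, ph$labels)
  vol <- loadVolume(img_path)
  expect_identical(dim(vol), dim(ph$image))        # 4D file read back channel-first
  expect_lt(max(abs(vol - ph$image)), 1e-6)
  expect_equal(attr(vol, "spacing"), c(1, 1, 1))
  lab <- loadLabels(lbl_path)
  expect_identical(lab, ph$labels)
  expect_error(loadLabels(lbl_path, image_shape = c(8L, 16L, 16L)), "does not match")
  expect_error(loadVolume(file.path(td, "missing.nii.gz")), "not found")
})
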