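wmh_phantom <- function() {
  memo("wmh_phantom", {
    specs <- list(lesion_spec("left", c(-20, 10, 18), 6, "wmh"),
                  lesion_spec("right", c(22, -15, 15), 5, "wmh"),
                  lesion_spec("left", c(-15, -30, 20), 4, "wmh"))
    make_head_phantom(phantom_config(modality = "mr", lesion_specs = specs,
                                     seed = 11, psf_mm = 0.5, noise_sd = 1.5,
                                     grid_shape = c(96, 96, 96),
                                     spacing_mm = c(2, 2, 2)))
  })
}

wmh_ranges <- list(t1 = c(100, 130), t2 = c(165, 235), pd = c(170, 215))

test_that("multi-modal thresholding recovers the planted WMH loci", {
  ph <- wmh_phantom()
  seg <- segment_wmh(ph$volume, ph$t2, ph$pd, wmh_ranges,
                     brain_mask = ph$brain_mask)
  truth <- ph$lesion_mask$data != 0
  found <- seg$mask$data != 0
  expect_gte(sum(truth & found) / sum(truth), 0.95)
  lab <- label_components(found)
  expect_equal(max(lab), 3L)         # three loci, no false components
  # and the contour product rasterizes back to the same mask
  expect_identical(mask_from_contours(seg$contours)$data != 0, found)
})

test_that("WMH segmentation uses intersection semantics", {
  ph <- wmh_phantom()
  # full-span ranges: the mask degenerates to the brain mask
  full <- list(t1 = c(-Inf, Inf), t2 = c(-Inf, Inf), pd = c(-Inf, Inf))
  seg <- segment_wmh(ph$volume, ph$t2, ph$pd, full, brain_mask = ph$brain_mask)
  expect_identical(seg$mask$data != 0, ph$brain_mask$data != 0)
  # excluding one modality removes a blob entirely
  r2 <- wmh_ranges; r2$t2 <- c(300, 400)
  seg2 <- segment_wmh(ph$volume, ph$t2, ph$pd, r2, brain_mask = ph$brain_mask)
  expect_equal(sum(seg2$mask$data), 0L)
  # mismatched grids are rejected
  small <- vol3d(array(0, c(4, 4, 4)), c(2, 2, 2), c(0, 0, 0))
  expect_error(segment_wmh(ph$volume, small, ph$pd, wmh_ranges), "mismatch")
})

test_that("WMH quantification counts loci and flags periventricular ones", {
  grid <- vol3d(array(0L, c(32, 32, 32)), c(1, 1, 1), c(0, 0, 0))
  vent <- grid; vent$data[14:18, 14:18, 14:18] <- 1L
  m <- grid
  m$data[20:24, 14:18, 14:18] <- 1L    # ~0.125 ml, near the ventricle
  m$data[28:30, 28:30, 28:30] <- 1L    # far corner
  rep <- quantify_wmh(m, vent)
  expect_equal(rep$n_loci, 2L)
  expect_equal(rep$total_volume_ml, sum(m$data) / 1000)
  expect_equal(sum(rep$loci$volume_ml), rep$total_volume_ml)
  near <- which.max(rep$loci$volume_ml)
  expect_true(rep$loci$periventricular[near])
  expect_false(all(rep$loci$periventricular))
  # overlapping blob: distance zero
  m2 <- grid; m2$data[16:18, 16:18, 16:18] <- 1L
  rep2 <- quantify_wmh(m2, vent)
  expect_equal(rep2$loci$distance_mm, 0)
  expect_true(rep2$loci$periventricular)
})

test_that("locus distances equal a brute-force nearest-surface search", {
  set.seed(9)
  grid <- vol3d(array(0L, c(32, 32, 32)), c(1, 1, 1), c(0, 0, 0))
  vent <- grid
  vent$data[10:14, 10:16, 12:15] <- 1L
  m <- grid
  m$data[22:24, 20:22, 20:21] <- 1L
  m$data[4:5, 25:26, 6:7] <- 1L
  rep <- quantify_wmh(m, vent)
  # brute force: loop over every lesion voxel x surface voxel pair
  vm <- vent$data != 0
  core <- strokeatlas:::erode_mask(vm, 1, c(1, 1, 1))
  surf <- which(vm & !core, arr.ind = TRUE)
  lab <- label_components(m$data != 0)
  for (i in seq_len(max(lab))) {
    les <- which(lab == i, arr.ind = TRUE)
    dmin <- Inf
    for (a in seq_len(nrow(les))) for (b in seq_len(nrow(surf)))
      dmin <- min(dmin, sqrt(sum((les[a, ] - surf[b, ])^2)))
    got <- rep$loci$distance_mm[rep$loci$locus == i]
    expect_equal(got, dmin, tolerance = 1e-9)
  }
})

test_that("an empty ventricle mask yields NA distances with a warning", {
  grid <- vol3d(array(0L, c(16, 16, 16)), c(1, 1, 1), c(0, 0, 0))
  m <- grid; m$data[4:6, 4:6, 4:6] <- 1L
  expect_warning(rep <- quantify_wmh(m, grid), "empty ventricle")
  expect_true(is.na(rep$loci$distance_mm))
})

test_that("CT brain extraction reaches Dice 0.95 and rejects degenerate input", {
  ph <- fx_atlas_phantom()
  bm <- extract_brain_ct(ph$volume)
  expect_gte(dice(bm$data != 0, ph$brain_mask$data != 0), 0.95)
  # the mask excludes every skull-valued voxel
  expect_equal(sum(bm$data != 0 & ph$volume$data > 220), 0L)
  air <- vol3d(array(rnorm(16^3, 0, 1), c(16, 16, 16)), c(2, 2, 2), c(0, 0, 0))
  expect_error(extract_brain_ct(air), "skull")
})

test_that("CSF removal strips ventricles but spares brain and lesions", {
  ph <- make_head_phantom(fx_det_config(seed = 12, lesion_specs = list(
    lesion_spec("left", c(-35, 10, 8), 13, "hypodense"))))
  ind <- individualize_atlas(fx_bundle(), ph$volume)
  bm <- extract_brain_ct(ph$volume)
  nocsf <- remove_csf(ph$volume, bm, ind$bundle$ventricle_template)
  removed <- bm$data != 0 & nocsf$data == 0
  vent <- ph$ventricle_mask$data != 0
  expect_gte(sum(removed & vent) / sum(vent), 0.9)
  nonvent <- ph$brain_mask$data != 0 & !vent
  expect_lte(sum(removed & nonvent) / sum(nonvent), 0.02)
  # the hypodense lesion (far from the template) is untouched
  les <- ph$lesion_mask$data != 0
  expect_lte(sum(removed & les) / sum(les), 0.02)
  # template with no CSF-valued voxels: nothing removed
  far <- ind$bundle$ventricle_template
  far$data[] <- 0L
  idx <- round(strokeatlas:::world_to_index(ph$volume, c(40, 20, 0)))
  far$data[idx[1] + (-2:2), idx[2] + (-2:2), idx[3] + (-2:2)] <- 1L
  noop <- remove_csf(ph$volume, bm, far, dilate_mm = 0)
  expect_identical(noop$data, bm$data)
  empty <- far; empty$data[] <- 0L
  expect_error(remove_csf(ph$volume, bm, empty), "empty")
})

dwi_lesion_phantom <- function() memo("dwi_phantom",
  make_head_phantom(phantom_config(modality = "dwi", seed = 13,
    lesion_specs = list(lesion_spec("left", c(-28, 5, 5), 15.3, "hyperdense")))))

test_that("left/right PDF divergence segments a diffusion lesion", {
  ph <- dwi_lesion_phantom()
  pl <- extract_msp(ph$volume)
  seg <- segment_infarct_dwi(ph$volume, pl)
  truth <- ph$lesion_mask$data != 0
  expect_gte(dice(seg$mask$data != 0, truth), 0.7)
  tv <- sum(truth) * prod(ph$volume$spacing) / 1000
  expect_lt(abs(seg$volume_ml - tv) / tv, 0.2)
})

test_that("divergence segmentation is silent on symmetric input", {
  ph <- make_head_phantom(fx_small_config(seed = 13, modality = "dwi"))
  seg <- segment_infarct_dwi(ph$volume, extract_msp(ph$volume))
  expect_equal(sum(seg$mask$data), 0L)
})

test_that("divergence segmentation is mirror-equivariant and scale-free", {
  ph <- dwi_lesion_phantom()
  pl <- ph$truth_msp                   # exact x = 0 plane: flip == mirror
  seg <- segment_infarct_dwi(ph$volume, pl)
  # left-right flip of the array mirrors the output
  fl <- ph$volume
  fl$data <- fl$data[dim(fl$data)[1]:1, , ]
  segf <- segment_infarct_dwi(fl, pl)
  expect_identical(segf$mask$data, seg$mask$data[dim(seg$mask$data)[1]:1, , ])
  # global affine intensity rescaling leaves the mask unchanged
  sc <- ph$volume
  sc$data <- 3.7 * sc$data + 120
  segs <- segment_infarct_dwi(sc, pl)
  expect_identical(segs$mask$data, seg$mask$data)
})

test_that("grossly unequal hemispheres trigger a warning", {
  ph <- dwi_lesion_phantom()
  off <- plane3d(c(1, 0, 0), 25)       # badly offset plane
  expect_warning(segment_infarct_dwi(ph$volume, off), "hemisphere")
})
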