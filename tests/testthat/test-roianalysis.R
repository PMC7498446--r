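test_that("ROI statistics follow the population conventions", {
  # 2-voxel toy: values 100 and 120 -> mean 110, population SD 10
  v <- vol3d(array(c(100, 120, 0, 0, 0, 0, 0, 0), c(2, 2, 2)), c(1, 1, 1),
             c(0, 0, 0))
  lab <- vol3d(array(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), c(2, 2, 2)),
               c(1, 1, 1), c(0, 0, 0))
  st <- roi_stats(v, lab)
  expect_equal(st$mean, 110)
  expect_equal(st$sd, 10)
  expect_equal(st$n, 2L)
  expect_lte(st$peak, 1)
})

test_that("uniform volumes give every ROI that intensity", {
  b <- fx_bundle()
  v <- vol3d(array(77, dim(b$anatomy$data)), b$anatomy$spacing,
             b$anatomy$origin)
  st <- roi_stats(v, b$anatomy)
  expect_true(all(st$mean == 77))
  expect_true(all(st$sd == 0))
})

test_that("ROIs fully removed by the mask are omitted with a warning", {
  b <- fx_bundle()
  v <- vol3d(array(50, dim(b$anatomy$data)), b$anatomy$spacing,
             b$anatomy$origin)
  m <- b$ventricle_template
  m$data <- 1L - m$data                # mask removes exactly the ventricles
  m <- vol3d(m$data, m$spacing, m$origin)
  expect_warning(st <- roi_stats(v, b$anatomy, mask = m), "omitted")
  vent_codes <- b$legend$code[grepl("ventricle", b$legend$name)]
  expect_false(any(vent_codes %in% st$code))
})

test_that("a symmetric phantom is reported as not detected", {
  r <- detect_case("det_sym", list(), 21)
  expect_equal(r$report$diagnosis, "not_detected")
  expect_equal(nrow(r$report$findings), 0L)
})

test_that("a hypodense territorial lesion is diagnosed as infarct", {
  specs <- list(lesion_spec("left", c(-36, -10, 6), 25, "hypodense"))
  r <- detect_case("det_inf", specs, 22, noise = 0)
  expect_equal(r$report$diagnosis, "infarct")
  f <- r$report$findings
  expect_true(all(f$side == "left"))
  expect_true(all(f$kind == "hypodense"))
  terr <- f[f$atlas == "territories", ]
  expect_gte(nrow(terr), 1L)
  expect_true(any(grepl("MCA", terr$label)))
  # the anatomy parcels the lesion overlaps are named
  expect_true(any(grepl("deep gray|white matter|parietal|temporal",
                        f$overlaps)))
})

test_that("territory finding slices match the lesion's slice span", {
  specs <- list(lesion_spec("left", c(-36, -10, 6), 25, "hypodense"))
  r <- detect_case("det_inf", specs, 22, noise = 0)
  ph <- make_head_phantom(fx_det_config(seed = 22, noise_sd = 0,
                                        lesion_specs = specs))
  f <- r$report$findings
  tf <- f[f$atlas == "territories", ][1, ]
  sl <- as.integer(strsplit(tf$slices, ",")[[1]])
  tmask <- r$ind$bundle$territories$data == tf$code
  tru <- range(which(apply(ph$lesion_mask$data != 0 & tmask, 3, any)))
  expect_lte(abs(min(sl) - tru[1]), 2)
  expect_lte(abs(max(sl) - tru[2]), 2)
})

test_that("a hyperdense core inside an infarct flags hemorrhagic transformation", {
  specs <- list(lesion_spec("left", c(-30, -5, 2), 20, "hypodense"),
                lesion_spec("left", c(-25, -2, 0), 11, "hyperdense"))
  r <- detect_case("det_ht", specs, 23)
  expect_equal(r$report$diagnosis, "infarct_with_hemorrhagic_transformation")
  expect_setequal(unique(r$report$findings$kind),
                  c("hypodense", "hyperdense"))
})

test_that("mirroring the scan swaps sides but preserves the diagnosis", {
  specs <- list(lesion_spec("left", c(-36, -10, 6), 25, "hypodense"))
  r <- detect_case("det_inf", specs, 22, noise = 0)
  ph <- make_head_phantom(fx_det_config(seed = 22, noise_sd = 0,
                                        lesion_specs = specs))
  fl <- ph$volume
  fl$data <- fl$data[dim(fl$data)[1]:1, , ]
  rf <- memo("det_inf_flip", fx_detect(list(volume = fl)))
  expect_equal(rf$report$diagnosis, "infarct")
  expect_true(all(rf$report$findings$side == "right"))
})

test_that("growing a hypodense lesion never un-detects the infarct", {
  for (rad in c(25, 29)) {
    key <- paste0("det_mono_", rad)
    r <- detect_case(key, list(lesion_spec("left", c(-36, -10, 6), rad,
                                           "hypodense")), 22, noise = 0)
    expect_equal(r$report$diagnosis, "infarct")
  }
})

test_that("ROI quantification matches a brute-force per-voxel tally", {
  set.seed(5)
  lab <- vol3d(array(sample(0:3, 20^3, replace = TRUE), c(20, 20, 20)),
               c(1, 1, 1), c(0, 0, 0))
  roi <- vol3d(array(0L, c(20, 20, 20)), c(1, 1, 1), c(0, 0, 0))
  roi$data[5:15, 5:15, 5:15] <- 1L
  q <- quantify_roi(roi, lab)
  # oracle: plain loop
  sel <- roi$data != 0
  counts <- table(lab$data[sel])
  for (i in seq_len(nrow(q$structures))) {
    cd <- as.character(q$structures$code[i])
    expect_equal(q$structures$volume_cm3[i], as.numeric(counts[cd]) / 1000)
    expect_equal(q$structures$percent[i],
                 as.numeric(counts[cd]) / sum(counts) * 100)
  }
  expect_equal(sum(q$structures$percent), 100, tolerance = 0.1)
  expect_equal(sum(q$structures$volume_cm3), q$totals$roi_volume_cm3,
               tolerance = 1e-9)
  expect_error(quantify_roi(vol3d(array(0L, c(20, 20, 20)), c(1, 1, 1),
                                  c(0, 0, 0)), lab), "empty ROI")
})

test_that("contained and split ROIs report the expected percentages", {
  lab <- vol3d(array(1L, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0))
  lab$data[6:10, , ] <- 2L
  roi <- vol3d(array(0L, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0))
  roi$data[2:4, 2:4, 2:4] <- 1L        # fully inside label 1
  q1 <- quantify_roi(roi, lab)
  expect_equal(q1$structures$percent, 100)
  roi$data[] <- 0L
  roi$data[4:7, 4:7, 4:7] <- 1L        # half in each by construction
  q2 <- quantify_roi(roi, lab)
  expect_equal(sort(q2$structures$percent), c(50, 50), tolerance = 1)
})

test_that("thrombolysis ratios and flags follow the strict thresholds", {
  b <- fx_bundle()
  legend <- b$legend
  terr <- b$territories
  lm_codes <- legend$code[legend$laterality == "left" &
                          grepl("MCA", legend$name)]
  mca <- array(terr$data %in% lm_codes, dim(terr$data))
  # infarct occupying exactly half the left MCA territory (by voxel parity)
  idx <- which(mca)
  inf <- vol3d(array(0L, dim(terr$data)), terr$spacing, terr$origin)
  inf$data[idx[seq_len(floor(length(idx) / 2))]] <- 1L
  pen <- vol3d(array(0L, dim(terr$data)), terr$spacing, terr$origin)
  pen$data[idx] <- 1L                  # penumbra = 2x infarct volume
  ta <- assess_thrombolysis(inf, terr, legend, pen)
  expect_equal(ta$infarct_to_MCA_ratio, floor(length(idx) / 2) / length(idx),
               tolerance = 1e-12)
  expect_true(ta$exceeds_one_third)
  expect_false(ta$exceeds_one_half)    # exactly one half is not "greater"
  expect_equal(ta$mismatch_ratio, length(idx) / floor(length(idx) / 2),
               tolerance = 1e-9)
  expect_equal(ta$side, "left")
  expect_equal(ta$MCA_terminal_ratio + 0, sum(
    inf$data != 0 & terr$data == legend$code[legend$name == "left MCA terminal"]) /
    sum(terr$data == legend$code[legend$name == "left MCA terminal"]))
})

test_that("an infarct confined to the PCA leaves the MCA ratio at zero", {
  b <- fx_bundle()
  terr <- b$territories
  pca <- terr$data == b$legend$code[b$legend$name == "left PCA"]
  inf <- vol3d(array(as.integer(pca), dim(terr$data)), terr$spacing,
               terr$origin)
  ta <- assess_thrombolysis(inf, terr, b$legend)
  expect_equal(ta$infarct_to_MCA_ratio, 0)
  expect_equal(ta$infarct_to_PCA_ratio, 1)
  expect_null(ta$mismatch_ratio)
})

test_that("an empty infarct warns and reports zero ratios", {
  b <- fx_bundle()
  inf <- vol3d(array(0L, dim(b$territories$data)), b$territories$spacing,
               b$territories$origin)
  expect_warning(ta <- assess_thrombolysis(inf, b$territories, b$legend),
                 "empty infarct")
  expect_equal(ta$infarct_to_MCA_ratio, 0)
})
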