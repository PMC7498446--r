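test_that("a one-voxel slab degenerates to the resampled MSP slice", {
  ph <- make_head_phantom(fx_small_config(seed = 21, noise_sd = 0))
  mp <- mip_slab(ph$volume, ph$truth_msp, width_mm = ph$volume$spacing[1])
  # compare against direct plane resampling
  fr <- mp$frame
  uu <- rep(mp$u, times = length(mp$v)); vv <- rep(mp$v, each = length(mp$u))
  pts <- cbind(fr$origin[1] + uu * fr$eu[1] + vv * fr$ev[1],
               fr$origin[2] + uu * fr$eu[2] + vv * fr$ev[2],
               fr$origin[3] + uu * fr$eu[3] + vv * fr$ev[3])
  ref <- matrix(sample_trilinear(ph$volume, pts), length(mp$u))
  ok <- !is.na(ref) & !is.na(mp$image)
  expect_equal(mp$image[ok], ref[ok])
})

test_that("the MIP dominates the central slice and catches bright dots", {
  ph <- make_head_phantom(fx_small_config(seed = 21, noise_sd = 0))
  v <- ph$volume
  # plant a bright dot 4 mm off-midline (inside a 10 mm slab)
  idx <- round(strokeatlas:::world_to_index(v, c(4, 0, 0)))
  v$data[idx[1], idx[2], idx[3]] <- 600
  thin <- mip_slab(v, ph$truth_msp, width_mm = v$spacing[1])
  wide <- mip_slab(v, ph$truth_msp, width_mm = 12)
  ok <- !is.na(thin$image) & !is.na(wide$image)
  expect_true(all(wide$image[ok] >= thin$image[ok] - 1e-9))
  # the dot is visible only in the wide slab
  expect_gt(max(wide$image, na.rm = TRUE), 300)
  expect_lt(max(thin$image, na.rm = TRUE), 300)
})

test_that("cortex outline recovers a synthetic disk boundary", {
  img <- matrix(0, 64, 64)
  u <- seq(-31.5, 31.5, by = 1); v <- u
  rr <- outer(u, v, function(a, b) sqrt(a^2 + b^2))
  img[rr < 20] <- 100
  mp <- structure(list(image = img, u = u, v = v,
                       frame = list(origin = c(0, 0, 0), eu = c(0, 1, 0),
                                    ev = c(0, 0, 1), normal = c(1, 0, 0))),
                  class = "mip_image")
  fid <- cortex_outline(mp)
  expect_gte(nrow(fid), 64)
  rad <- sqrt(rowSums(fid^2))
  expect_true(all(abs(rad - 20) <= 1))
  # an empty image errors
  mp$image[] <- 0
  expect_error(cortex_outline(mp), "threshold|empty")
})

test_that("phantom MIP fiducials lie on the analytic brain ellipse", {
  ph <- make_head_phantom(fx_small_config(seed = 22))
  mp <- mip_slab(ph$volume, ph$truth_msp, 10)
  fid <- cortex_outline(mp)
  # central sagittal cross-section: semi-axes (B_y, B_z) around the centre
  e <- (fid[, 1] / 75)^2 + (fid[, 2] / 55)^2
  r <- sqrt(e)                          # ~1 on the boundary
  expect_true(all(abs(r - 1) < 0.06))   # within ~1 voxel relative error
})

test_that("the direct ellipse fit recovers exact and jittered samples", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  pts <- cbind(5 + 86 * cos(th), -3 + 58 * sin(th))
  ft <- fit_ellipse(pts)
  expect_lt(abs(ft$a - 86), 0.1)
  expect_lt(abs(ft$b - 58), 0.1)
  expect_equal(ft$center, c(5, -3), tolerance = 1e-6)
  # circle degenerates to a == b
  fc <- fit_ellipse(cbind(10 * cos(th), 10 * sin(th)))
  expect_lt(abs(fc$a - fc$b), 1e-6)
  # 1 mm isotropic jitter: parameters recovered within 1 mm
  set.seed(7)
  jit <- pts + matrix(rnorm(length(pts), 0, 1), ncol = 2)
  fj <- fit_ellipse(jit)
  expect_lt(abs(fj$a - 86), 1)
  expect_lt(abs(fj$b - 58), 1)
  expect_error(fit_ellipse(pts[1:5, ]), "6 points")
  expect_error(fit_ellipse(cbind(1:20, 2 * (1:20))), "degenerate")
})

test_that("default landmark fractions reproduce the atlas landmarks", {
  # the calibration oracle: an exact fit of the atlas-space ellipse must give
  # back the stored atlas landmarks
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  pts <- cbind(-16 + 86 * cos(th), 15 + 59 * sin(th))
  ft <- fit_ellipse(pts)
  lm <- landmarks_from_ellipse(ft, lateral = c(-68, 68))
  ref <- atlas_landmarks()
  expect_lt(max(abs(lm$AC - c(0, ref$AC[2], ref$AC[3]))), 0.5)
  expect_lt(max(abs(lm$PC - c(0, ref$PC[2], ref$PC[3]))), 0.5)
  expect_equal(lm$A, ref$A, tolerance = 0.5)
  expect_equal(lm$P, ref$P, tolerance = 0.5)
  expect_equal(lm$S, ref$S, tolerance = 0.5)
  expect_equal(lm$I, ref$I, tolerance = 0.5)
  expect_equal(lm$CC_top, ref$CC_top, tolerance = 0.5)
  expect_equal(lm$OF_ventral, ref$OF_ventral, tolerance = 0.5)
})

test_that("landmark placement is homogeneous under ellipse scaling", {
  ft <- structure(list(center = c(4, -2), a = 80, b = 50, orientation = 0,
                       rms = 0), class = "ellipse_fit")
  ft2 <- ft; ft2$a <- 160; ft2$b <- 100
  lm <- landmarks_from_ellipse(ft, lateral = c(-60, 60))
  lm2 <- landmarks_from_ellipse(ft2, lateral = c(-120, 120))
  # cortical extremes double about the centre
  expect_equal(lm2$A - ft$center[1], 2 * (lm$A - ft$center[1]))
  expect_equal(lm2$S - ft$center[2], 2 * (lm$S - ft$center[2]))
  expect_equal(lm2$AC[2:3] - ft$center, 2 * (lm$AC[2:3] - ft$center))
  # A and P sit at centre +- a on the major axis
  expect_equal(lm$A, ft$center[1] + ft$a)
  expect_equal(lm$P, ft$center[1] - ft$a)
})

test_that("the piecewise-linear transform has the documented structure", {
  src <- atlas_landmarks()
  tgt <- landmark_set(AC = c(1, 2, 0), PC = c(1, -20, 0),
                      L = -60, R = 62, A = 66, P = -95, S = 70, I = -40,
                      CC_top = 33, OF_ventral = -14)
  t12 <- build_transform(src, tgt, extended = FALSE)
  expect_equal(t12$n_regions, 12L)
  expect_equal(t12$dof, 13L)
  t24 <- build_transform(src, tgt, extended = TRUE)
  expect_equal(t24$n_regions, 24L)
  expect_equal(t24$dof, 15L)
  # identity when source == target
  tid <- build_transform(src, src, extended = TRUE)
  set.seed(3)
  pts <- cbind(runif(50, -60, 60), runif(50, -100, 65), runif(50, -40, 70))
  expect_equal(apply_to_points(tid, pts), pts, tolerance = 1e-12)
  # landmarks map exactly
  expect_equal(as.vector(apply_to_points(t24, rbind(src$AC))),
               tgt$AC, tolerance = 1e-12)
  # ordering violations error
  bad <- tgt; bad$A <- -100
  expect_error(landmark_set(bad$AC, bad$PC, bad$L, bad$R, bad$A, bad$P,
                            bad$S, bad$I), "ordering")
  # extended without extended landmarks errors
  noext <- landmark_set(tgt$AC, tgt$PC, tgt$L, tgt$R, tgt$A, tgt$P,
                        tgt$S, tgt$I)
  expect_error(build_transform(src, noext, extended = TRUE), "extended")
})

test_that("the transform inverts exactly and is continuous across regions", {
  src <- atlas_landmarks()
  tgt <- landmark_set(AC = c(-2, 3, 1), PC = c(-2, -22, 1),
                      L = -64, R = 59, A = 72, P = -99, S = 69, I = -47,
                      CC_top = 35, OF_ventral = -12)
  tr <- build_transform(src, tgt, extended = TRUE)
  inv <- invert_transform(tr)
  set.seed(4)
  pts <- cbind(runif(1000, -67, 67), runif(1000, -101, 69),
               runif(1000, -43, 73))
  back <- apply_to_points(inv, apply_to_points(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  # continuity: approach a shared boundary plane (y = PC_y) from both sides
  eps <- 1e-9
  p_lo <- apply_to_points(tr, c(10, src$PC[2] - eps, 20))
  p_hi <- apply_to_points(tr, c(10, src$PC[2] + eps, 20))
  expect_lt(max(abs(p_lo - p_hi)), 1e-6)
  # clamping warns
  expect_warning(apply_to_points(tr, c(500, 0, 0)), "clamped")
})

test_that("label resampling maps the atlas onto a shifted grid", {
  b <- fx_bundle()
  src <- b$space$landmarks
  tgt <- landmark_set(AC = src$AC + c(0, 5, 0), PC = src$PC + c(0, 5, 0),
                      L = src$L, R = src$R, A = src$A + 5, P = src$P + 5,
                      S = src$S, I = src$I,
                      CC_top = src$CC_top, OF_ventral = src$OF_ventral)
  tr <- build_transform(src, tgt, extended = TRUE)
  out <- apply_to_labels(tr, b$anatomy, b$anatomy)
  # a pure +5 mm anterior shift moves labels by +5 mm
  idx <- round(strokeatlas:::world_to_index(b$anatomy, c(30, 5, 10)))
  src_idx <- round(strokeatlas:::world_to_index(b$anatomy, c(30, 0, 10)))
  expect_equal(out$data[idx[1], idx[2], idx[3]],
               b$anatomy$data[src_idx[1], src_idx[2], src_idx[3]])
})

test_that("identity-regime individualization reproduces the atlas", {
  ph <- fx_atlas_phantom()
  b <- fx_bundle()
  res <- individualize_atlas(b, ph$volume)
  # identity regime: the mapped labels equal the atlas labels resampled
  # plainly onto the scan grid
  ref_an <- strokeatlas:::resample_onto(b$anatomy, ph$volume, nearest = TRUE)
  ref_te <- strokeatlas:::resample_onto(b$territories, ph$volume, nearest = TRUE)
  expect_gte(mean(res$bundle$anatomy$data == ref_an$data), 0.99)
  expect_gte(mean(res$bundle$territories$data == ref_te$data), 0.99)
  # total labeled volume matches the extracted brain volume within 2%
  brain <- extract_brain_ct(ph$volume)
  ratio <- sum(res$bundle$anatomy$data > 0) / sum(brain$data != 0)
  expect_lt(abs(ratio - 1), 0.02)
})

test_that("an anteriorly stretched brain stretches the anterior parcels", {
  b <- fx_bundle()
  fr_codes <- b$legend$code[grepl("frontal", b$legend$name)]
  ext_y <- function(res, ph) {
    m <- array(res$bundle$anatomy$data %in% fr_codes,
               dim(res$bundle$anatomy$data))
    diff(range(vol_axes(ph$volume)[[2]][which(apply(m, 2, any))]))
  }
  ph <- make_head_phantom(phantom_config(grid_shape = c(96, 108, 96),
                                         spacing_mm = c(2, 2, 2),
                                         brain_semi_mm = c(60, 90, 55),
                                         seed = 8))
  ph0 <- make_head_phantom(fx_det_config(seed = 8))
  r1 <- individualize_atlas(b, ph$volume)
  r0 <- individualize_atlas(b, ph0$volume)
  expect_lt(abs(ext_y(r1, ph) / ext_y(r0, ph0) - 1.2), 0.05 * 1.2)
})

test_that("a rotated scan keeps territories mirror-consistent about its MSP", {
  b <- fx_bundle()
  ph <- make_head_phantom(fx_det_config(seed = 8, rotation_deg = c(20, 0, 0)))
  res <- individualize_atlas(b, ph$volume)
  lmt <- b$legend[b$legend$laterality == "left" &
                  grepl("MCA terminal", b$legend$name), ]
  terr <- res$bundle$territories
  lmask <- vol3d(array(as.integer(terr$data == lmt$code), dim(terr$data)),
                 terr$spacing, terr$origin)
  mir <- mirror_volume(lmask, res$msp, nearest = TRUE)
  rmask <- terr$data == lmt$mirror_code
  jac <- sum(mir$data != 0 & rmask) / sum(mir$data != 0 | rmask)
  expect_gte(jac, 0.9)
})

test_that("the statistical landmark path works without visible commissures", {
  # 6 mm slices: no commissure-scale structure survives, the ellipse path
  # must still produce a valid landmark set
  ph <- make_head_phantom(phantom_config(seed = 31, slice_thickness_mm = 6))
  res <- individualize_atlas(fx_bundle(), ph$volume)
  expect_s3_class(res$landmarks, "landmark_set")
  expect_gt(sum(res$bundle$anatomy$data > 0), 100000)
})
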