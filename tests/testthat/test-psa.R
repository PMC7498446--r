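test_that("case normalization is the identity for atlas-space cases", {
  space <- fx_psa_space4()
  cs <- fx_toy_case("id1", c(-20, -10, 10), 12, 3, space = space)
  m0 <- mask_from_contours(cs$lesion_contours)
  m1 <- normalize_case(cs, space)
  expect_gte(dice(m1$data != 0, m0$data != 0), 0.98)
  expect_error(normalize_case(
    case_record("x", cs$lesion_contours, list(p = 1), to_psa = 42), space),
    "invalid normalization")
})

test_that("a known anisotropic transform preserves lesion volume within 10%", {
  space <- fx_psa_space4()
  src <- atlas_landmarks()
  # scan space: atlas stretched 1.2x anteriorly
  tgt <- landmark_set(AC = src$AC, PC = src$PC, L = src$L, R = src$R,
                      A = src$A * 1.2, P = src$P * 1.2, S = src$S, I = src$I,
                      CC_top = src$CC_top, OF_ventral = src$OF_ventral)
  tr <- build_transform(src, tgt, extended = TRUE)
  # lesion drawn in scan space
  scan_grid <- vol3d(array(0L, c(60, 70, 60)), c(3, 3, 3),
                     -c(59, 69, 59) / 2 * 3)
  les <- strokeatlas:::lesion_sphere_mask(scan_grid, c(-20, -30, 10), 14)
  cs <- case_record("aniso", contours_from_mask(les), list(p = 1),
                    to_psa = tr)
  m <- normalize_case(cs, space)
  v_scan <- sum(les$data) * prod(scan_grid$spacing) / 1000
  v_psa <- sum(m$data) * prod(space$spacing) / 1000
  # normalization undoes the anterior stretch: volume shrinks by ~1/1.2
  expect_lt(abs(v_psa * 1.2 - v_scan) / v_scan, 0.1)
})

test_that("PSA aggregation matches a brute-force voxel loop for all schemes", {
  space <- fx_toy_space()
  cases <- list(fx_toy_case("a", c(-4, 0, 0), 6, 2),
                fx_toy_case("b", c(4, 0, 0), 6, 4),
                fx_toy_case("c", c(0, 4, 0), 5, 3),
                fx_toy_case("d", c(0, -4, 2), 5, 5),
                fx_toy_case("e", c(2, 2, 2), 4, 1))
  masks <- lapply(cases, function(cs) normalize_case(cs, space)$data != 0)
  vals <- vapply(cases, function(cs) cs$variables$p, 0)
  wts <- vapply(cases, function(cs) 1 / cs$variables$infarct_volume_ml, 0)
  covered <- which(Reduce(`+`, masks) > 0)
  set.seed(1)
  probe <- sample(covered, 25)
  for (sch in psa_schemes()) {
    psa <- build_psa(cases, "p", sch, space)
    for (ix in probe) {
      pres <- vapply(masks, function(m) m[ix], TRUE)
      expected <- switch(sch,
        mean_global_n = sum(vals[pres]) / length(cases),
        mean_coverage = mean(vals[pres]),
        median = median(vals[pres]),
        trimmed_mean = mean(vals[pres], trim = 0.2),
        min = min(vals[pres]), max = max(vals[pres]),
        size_weighted_mean = sum((vals * wts)[pres]) / sum(wts[pres]),
        sum = sum(vals[pres]))
      expect_equal(psa$aggregate$data[ix], expected, tolerance = 1e-12)
      expect_equal(psa$coverage$data[ix], sum(pres))
    }
    # aggregate is zero wherever coverage is zero
    expect_true(all(psa$aggregate$data[psa$coverage$data == 0] == 0))
  }
})

test_that("the two mean schemes differ exactly by their divisor", {
  space <- fx_toy_space()
  cases <- list(fx_toy_case("x", c(-2, 0, 0), 5, 2),
                fx_toy_case("y", c(2, 0, 0), 5, 4))
  pc <- build_psa(cases, "p", "mean_coverage", space)
  pg <- build_psa(cases, "p", "mean_global_n", space)
  ov <- pc$coverage$data == 2L
  expect_true(all(pc$aggregate$data[ov] == 3))
  expect_true(all(pg$aggregate$data[ov] == 3))
  ex <- pc$coverage$data == 1L
  expect_setequal(unique(pg$aggregate$data[ex]), c(1, 2))
  expect_setequal(unique(pc$aggregate$data[ex]), c(2, 4))
  # single case: the map equals the value on its ROI
  p1 <- build_psa(cases[1], "p", "mean_coverage", space)
  expect_setequal(unique(p1$aggregate$data), c(0, 2))
  expect_error(build_psa(cases, "missing_par", "mean_coverage", space),
               "case x")
})

test_that("coverage conserves the total normalized ROI volume", {
  space <- fx_toy_space()
  cases <- list(fx_toy_case("a", c(-4, 0, 0), 6, 2),
                fx_toy_case("b", c(4, 0, 0), 6, 4),
                fx_toy_case("c", c(0, 4, 0), 5, 3))
  psa <- build_psa(cases, "p", "mean_coverage", space)
  roi_sizes <- vapply(cases,
                      function(cs) sum(normalize_case(cs, space)$data != 0), 0L)
  expect_equal(sum(psa$coverage$data), sum(roi_sizes))
})

test_that("incremental update equals a batch rebuild for mean_coverage", {
  space <- fx_toy_space()
  cases <- list(fx_toy_case("a", c(-4, 0, 0), 6, 2),
                fx_toy_case("b", c(4, 0, 0), 6, 4),
                fx_toy_case("c", c(0, 4, 0), 5, 3),
                fx_toy_case("d", c(0, -4, 2), 5, 5))
  p3 <- build_psa(cases[1:3], "p", "mean_coverage", space)
  inc <- psa_add_case(p3, cases[[4]])
  full <- build_psa(cases, "p", "mean_coverage", space)
  expect_equal(inc$aggregate$data, full$aggregate$data, tolerance = 1e-12)
  expect_identical(inc$coverage$data, full$coverage$data)
  expect_error(psa_add_case(build_psa(cases[1:3], "p", "median", space),
                            cases[[4]]), "mean_coverage")
})

test_that("case selection respects quantile ranges and leave-one-out", {
  grid <- fx_psa_space4()
  cases <- make_cohort(cohort_spec(24, seed = 31), grid = grid)
  target <- cases[[5]]
  # no constraints: everything except the target
  sel0 <- constrain_cases(cases, target)
  expect_length(sel0, 23L)
  expect_false(target$id %in% vapply(sel0, function(cs) cs$id, ""))
  # volume constraint: all selected cases share the target's quartile
  sel1 <- constrain_cases(cases, target, "infarct_volume_ml")
  vols <- vapply(cases[vapply(cases, function(cs) cs$id, "") != target$id],
                 function(cs) cs$variables$infarct_volume_ml, 0)
  qs <- quantile(vols, probs = seq(0, 1, 0.25), names = FALSE)
  qs[1] <- -Inf; qs[5] <- Inf
  tb <- findInterval(target$variables$infarct_volume_ml, qs)
  for (cs in sel1)
    expect_equal(findInterval(cs$variables$infarct_volume_ml, qs), tb)
  # target excluded even though it satisfies its own constraint
  expect_false(target$id %in% vapply(sel1, function(cs) cs$id, ""))
  # an impossible combination of constraints errors
  space <- fx_psa_space4()
  mk <- function(id, a, b) {
    cs <- fx_toy_case(id, c(0, -16, 15), 10, 1, space = space)
    cs$variables$va <- a; cs$variables$vb <- b
    cs
  }
  cc <- list(mk("c1", 1, 1), mk("c2", 1, 1), mk("c3", 10, 10),
             mk("c4", 10, 10), mk("tgt", 1, 10))
  expect_error(constrain_cases(cc[1:4], cc[[5]],
                               list(list(variable = "va", n_ranges = 2),
                                    list(variable = "vb", n_ranges = 2))),
               "no comparable")
})

test_that("PSA prediction matches a sort-based oracle", {
  space <- fx_toy_space()
  cases <- list(fx_toy_case("a", c(-4, 0, 0), 6, 2),
                fx_toy_case("b", c(4, 0, 0), 6, 4))
  psa <- build_psa(cases, "p", "mean_coverage", space)
  roi <- strokeatlas:::lesion_sphere_mask(space, c(0, 0, 0), 6)
  pred <- predict_psa(psa, roi)
  sel <- roi$data != 0 & psa$coverage$data > 0
  x <- sort(psa$aggregate$data[sel])
  expect_equal(pred$mean, mean(x))
  expect_equal(pred$p50, unname(quantile(x, 0.5)))
  expect_equal(pred$p25, unname(quantile(x, 0.25)))
  expect_equal(pred$p75, unname(quantile(x, 0.75)))
  expect_true(pred$p25 <= pred$p50 && pred$p50 <= pred$p75)
  expect_equal(pred$n_voxels, sum(sel))
  # constant PSA over the ROI
  c1 <- build_psa(cases[1], "p", "mean_coverage", space)
  roi1 <- strokeatlas:::lesion_sphere_mask(space, c(-4, 0, 0), 3)
  pr1 <- predict_psa(c1, roi1)
  expect_equal(pr1$mean, 2); expect_equal(pr1$p50, 2); expect_equal(pr1$sd, 0)
  # an ROI with no covered voxels errors
  far <- strokeatlas:::lesion_sphere_mask(space, c(14, 14, 14), 2)
  expect_error(predict_psa(psa, far), "no covered")
})

test_that("leave-one-out recovers location-determined outcomes", {
  grid <- fx_psa_space4()
  lin <- list(mRS_day90 = list(fn = function(c, v) 3 + 0.025 * c[1],
                               noise_sd = 0))
  co <- make_cohort(cohort_spec(40, outcome_names = "mRS_day90",
                                coupling = lin, seed = 6), grid = grid)
  r <- loo_evaluate(co, "mRS_day90", space = grid)
  expect_lte(r$overall_mae, 0.5)
  # constant outcome: zero error
  co0 <- make_cohort(cohort_spec(6, outcome_names = "mRS_day90",
    coupling = list(mRS_day90 = list(fn = function(c, v) 3, noise_sd = 0)),
    seed = 7), grid = grid)
  expect_equal(loo_evaluate(co0, "mRS_day90", space = grid)$overall_mae, 0)
})

test_that("tight volume constraints do not increase the prediction error", {
  grid <- fx_psa_space4()
  co <- make_cohort(cohort_spec(48, outcome_names = "mRS_day90", seed = 8),
                    grid = grid)
  mae_u <- loo_evaluate(co, "mRS_day90", space = grid)$overall_mae
  mae_c <- loo_evaluate(co, "mRS_day90", constraints = "infarct_volume_ml",
                        space = grid)$overall_mae
  expect_lte(mae_c, mae_u)
})

test_that("prediction error shrinks as the cohort grows", {
  grid <- fx_psa_space4()
  lin <- list(mRS_day90 = list(fn = function(c, v) 3 + 0.025 * c[1],
                               noise_sd = 0))
  e20 <- loo_evaluate(make_cohort(cohort_spec(20, outcome_names = "mRS_day90",
                                              coupling = lin, seed = 9),
                                  grid = grid), "mRS_day90",
                      space = grid)$overall_mae
  e100 <- loo_evaluate(make_cohort(cohort_spec(100, outcome_names = "mRS_day90",
                                               coupling = lin, seed = 9),
                                   grid = grid), "mRS_day90",
                       space = grid)$overall_mae
  expect_lt(e100, e20)
})

test_that("design enumeration validates its inputs", {
  expect_error(enumerate_design(0, c(4, 4), 1, 10), ">= 1")
  d <- enumerate_design(2, c(3, 3), 4, 10)
  expect_equal(d$instances_per_case, 18)
  expect_equal(d$total_instances, 18 * 4 * 10)
  expect_equal(d$total_case_processings, 18 * 4 * 10 * 9)
})

test_that("PSA maps survive a disk round trip", {
  space <- fx_toy_space()
  cases <- list(fx_toy_case("a", c(-4, 0, 0), 6, 2),
                fx_toy_case("b", c(4, 0, 0), 6, 4))
  psa <- build_psa(cases, "p", "mean_coverage", space)
  pre <- tempfile("psa")
  write_psa(psa, pre)
  agg <- read_volume(paste0(pre, "_aggregate.nii.gz"))
  cov <- read_volume(paste0(pre, "_coverage.nii.gz"))
  expect_equal(agg$data, psa$aggregate$data, tolerance = 1e-12)
  expect_equal(cov$data, psa$coverage$data + 0, tolerance = 1e-12)
})
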