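# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# the simplified atlas bundle (2 mm normalized grid)
fx_bundle <- function() memo("bundle", build_simplified_atlas())

# phantom with the normalized space's brain geometry, on a scan-resolution
# grid centred on the atlas brain (identity mapping regime)
fx_atlas_space_config <- function(seed = 7, ...) {
  sp <- strokeatlas:::atlas_space()
  shape <- c(128L, 144L, 128L)
  phantom_config(grid_shape = shape, spacing_mm = c(1.5, 1.5, 1.5),
                 origin_mm = sp$brain_center - (shape - 1) / 2 * 1.5,
                 brain_semi_mm = sp$brain_semi,
                 noise_sd = 2, seed = seed, ...)
}

fx_atlas_phantom <- function() memo("atlas_phantom",
                                    make_head_phantom(fx_atlas_space_config()))

# a small, quick phantom for geometry and contour tests (72^3, 2.6 mm)
fx_small_config <- function(seed = 1, ...)
  phantom_config(grid_shape = c(72, 72, 72), spacing_mm = c(2.6, 2.6, 2.6),
                 seed = seed, ...)

# a CT phantom at full scan resolution for detection pipelines
fx_det_config <- function(seed = 1, ...) phantom_config(seed = seed, ...)

# full detection pipeline on a phantom
fx_detect <- function(ph, thresholds = list(mean = 6, sd = 6, peak = 0.05)) {
  ind <- individualize_atlas(fx_bundle(), ph$volume)
  brain <- extract_brain_ct(ph$volume)
  nocsf <- remove_csf(ph$volume, brain, ind$bundle$ventricle_template)
  list(report = detect_stroke(ph$volume, ind$bundle, mask = nocsf,
                              thresholds = thresholds, msp = ind$msp),
       ind = ind, brain = brain, nocsf = nocsf)
}

# 16^3 toy grid for brute-force PSA oracles
fx_toy_space <- function() vol3d(array(0, c(16, 16, 16)), c(2, 2, 2),
                                 c(-15, -15, -15))

# normalized space at 4 mm: covers the whole brain but 8x fewer voxels
fx_psa_space4 <- function() {
  sp <- strokeatlas:::atlas_space()
  ctr <- sp$origin + (sp$shape - 1) / 2 * sp$spacing
  shape <- c(46L, 54L, 46L)
  vol3d(array(0, shape), c(4, 4, 4), ctr - (shape - 1) / 2 * 4)
}

fx_toy_case <- function(id, center, radius, value, space = fx_toy_space()) {
  m <- strokeatlas:::lesion_sphere_mask(space, center, radius)
  case_record(id, contours_from_mask(m),
              list(p = value,
                   infarct_volume_ml = sum(m$data) * prod(space$spacing) / 1000))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# memoized detection scenarios shared between the unit and acceptance suites
detect_case <- function(key, specs, seed, noise = 2) {
  memo(key, fx_detect(make_head_phantom(
    fx_det_config(seed = seed, noise_sd = noise, lesion_specs = specs))))
}
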