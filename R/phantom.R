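#' Head-phantom configuration
#'
#' Describes a procedurally generated head volume: a left-right symmetric
#' brain ellipsoid (gray-matter shell around a white-matter core) carrying an
#' interhemispheric fissure and paired lateral ventricles, wrapped in a
#' CSF-filled subarachnoid gap and a high-intensity skull shell (CT-style).
#' Perturbation axes follow the robustness studies the generator supports:
#' rigid rotation, additive noise, multiplicative bias field and thick-slice
#' acquisition.
#'
#' Intensities are on an 8-bit-like \[0, 255\] scale for the CT modality
#' (air 0, CSF 30, white matter 96, gray matter 106, skull 250, hypodense
#' lesion 75, hyperdense lesion 170). MR-style modalities (`"mr"`, `"dwi"`)
#' use modality-specific tissue means and a dark skull.
#'
#' @param grid_shape integer(3) voxels per axis (default 128^3).
#' @param spacing_mm numeric(3) voxel size (default 1.5 mm isotropic).
#' @param rotation_deg numeric(3) yaw/pitch/roll applied to the head about the
#'   grid centre (see [rotation_matrix()]).
#' @param noise_sd additive Gaussian noise SD in intensity units (>= 0).
#' @param psf_mm Gaussian point-spread-function sigma (mm) emulating scanner
#'   blur / partial volume; applied to the clean tissue volume (default 1).
#' @param texture_sd SD (intensity units) of the smooth intra-tissue texture
#'   added to gray and white matter (default 4). The texture field is exactly
#'   mirror-symmetric about the midsagittal plane, so it perturbs tissue
#'   appearance without breaking hemispheric symmetry.
#' @param texture_corr_mm correlation length of the texture field (default 8).
#' @param inhomogeneity_pct peak-to-peak percentage of the multiplicative
#'   low-order polynomial bias field (0 disables it).
#' @param lesion_specs list of [lesion_spec()] entries.
#' @param slice_thickness_mm optional acquisition resampling thickness along z.
#' @param seed integer RNG seed; generation is bit-identical for a fixed seed.
#' @param modality `"ct"` (default), `"mr"` (returns T1/T2/PD views) or
#'   `"dwi"` (single MR-like volume without a bright skull).
#' @param brain_semi_mm semi-axes of the brain ellipsoid (mm).
#' @param brain_offset_mm offset of the brain centre from the grid centre (mm).
#' @param origin_mm world coordinate of voxel (1,1,1); default centres the
#'   grid on the world origin.
#' @param skull logical; include the skull shell (forced off for `"dwi"`).
#' @param with_masks logical; set `FALSE` to skip generating the ground-truth
#'   mask volumes (faster, e.g. for MSP robustness sweeps that only need the
#'   intensity volume and the truth plane).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(128, 128, 128),
                           spacing_mm = c(1.5, 1.5, 1.5),
                           rotation_deg = c(0, 0, 0),
                           noise_sd = 2,
                           psf_mm = 1,
                           texture_sd = 4,
                           texture_corr_mm = 8,
                           inhomogeneity_pct = 0,
                           lesion_specs = list(),
                           slice_thickness_mm = NULL,
                           seed = 1L,
                           modality = c("ct", "mr", "dwi"),
                           brain_semi_mm = c(60, 75, 55),
                           brain_offset_mm = c(0, 0, 0),
                           origin_mm = NULL,
                           skull = TRUE,
                           with_masks = TRUE) {
  modality <- match.arg(modality)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three positive voxel counts")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (!all(is.finite(rotation_deg)) || length(rotation_deg) != 3L)
    stop("rotation_deg must be three finite angles")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inhomogeneity_pct < 0) stop("inhomogeneity_pct must be >= 0")
  for (ls in lesion_specs)
    if (!inherits(ls, "lesion_spec")) stop("lesion_specs must be lesion_spec objects")
  if (modality == "dwi") skull <- FALSE
  if (psf_mm < 0) stop("psf_mm must be >= 0")
  if (texture_sd < 0) stop("texture_sd must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 rotation_deg = as.numeric(rotation_deg), noise_sd = noise_sd,
                 psf_mm = psf_mm, texture_sd = texture_sd,
                 texture_corr_mm = texture_corr_mm,
                 inhomogeneity_pct = inhomogeneity_pct,
                 lesion_specs = lesion_specs,
                 slice_thickness_mm = slice_thickness_mm,
                 seed = as.integer(seed), modality = modality,
                 brain_semi_mm = as.numeric(brain_semi_mm),
                 brain_offset_mm = as.numeric(brain_offset_mm),
                 origin_mm = origin_mm, skull = isTRUE(skull),
                 with_masks = isTRUE(with_masks)),
            class = "phantom_config")
}

#' Lesion specification for the head phantom
#'
#' @param side `"left"` or `"right"` (checked against the centre coordinate).
#' @param center_mm lesion centre relative to the brain centre, in the
#'   unrotated phantom frame (x right, y anterior, z superior).
#' @param radius_mm sphere radius (> 0).
#' @param contrast `"hypodense"`, `"hyperdense"` or `"wmh"` (the latter only
#'   meaningful for the MR modality).
#' @param territory_hint optional free-text territory annotation.
#' @export
lesion_spec <- function(side = c("left", "right"), center_mm, radius_mm,
                        contrast = c("hypodense", "hyperdense", "wmh"),
                        territory_hint = NULL) {
  side <- match.arg(side)
  contrast <- match.arg(contrast)
  if (radius_mm <= 0) stop("lesion radius must be > 0")
  if ((side == "left" && center_mm[1] > 0) ||
      (side == "right" && center_mm[1] < 0))
    stop("lesion side label contradicts its centre x coordinate")
  structure(list(side = side, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, contrast = contrast,
                 territory_hint = territory_hint), class = "lesion_spec")
}

# modality intensity tables: tissue -> mean intensity
phantom_lut <- function(modality) {
  switch(modality,
    ct  = c(air = 0, csf = 30, gray = 106, white = 96, skull = 250,
            hypo = 75, hyper = 170, wmh = 96, falx = 150),
    dwi = c(air = 2, csf = 35, gray = 105, white = 95, skull = 20,
            hypo = 55, hyper = 180, wmh = 95, falx = 45),
    t1  = c(air = 5, csf = 40, gray = 120, white = 160, skull = 30,
            hypo = 100, hyper = 100, wmh = 112, falx = 75),
    t2  = c(air = 5, csf = 220, gray = 130, white = 100, skull = 20,
            hypo = 160, hyper = 160, wmh = 200, falx = 60),
    pd  = c(air = 5, csf = 180, gray = 140, white = 120, skull = 20,
            hypo = 150, hyper = 150, wmh = 190, falx = 70))
}

# tissue codes for the label volume
PHANTOM_CODES <- c(air = 0L, csf = 1L, gray = 2L, white = 3L,
                   ventricle = 4L, skull = 5L, lesion = 6L, falx = 7L)

#' Generate a ground-truthed head phantom
#'
#' The unrotated phantom is mirror-symmetric about its midsagittal plane; the
#' intensity volume is rotated by resampling with linear interpolation while
#' the ground truth (plane, landmarks, masks) is transformed analytically.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom_case` with elements `volume` (plus `t2`,
#'   `pd` for the MR modality), `truth_msp` ([plane3d()]), `truth_landmarks`
#'   (a [landmark_set()] in the unrotated frame), `truth_rotation`
#'   (list with `R`, `center`, `angles_deg`), `ventricle_mask`, `lesion_mask`,
#'   `brain_mask`, `tissue_labels` (all `vol3d` on the same grid) and `config`.
#' @export
make_head_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop("`config` must be a phantom_config")
  cfg <- config
  d <- cfg$grid_shape
  sp <- cfg$spacing_mm
  origin <- if (is.null(cfg$origin_mm)) -(d - 1) / 2 * sp else cfg$origin_mm
  proto <- vol3d(array(0, d), sp, origin)
  ctr <- vol_center(proto)
  bc <- ctr + cfg$brain_offset_mm            # brain centre, world mm
  B <- cfg$brain_semi_mm

  # lesion validity: centre must lie inside the brain ellipsoid
  for (i in seq_along(cfg$lesion_specs)) {
    ls <- cfg$lesion_specs[[i]]
    if (sum((ls$center_mm / B)^2) >= 1)
      stop(sprintf("lesion %d lies outside the brain", i))
  }

  pts <- grid_points(proto)
  labs_un <- phantom_tissues(pts, bc, B, cfg)           # unrotated labels
  R <- rotation_matrix(cfg$rotation_deg[1], cfg$rotation_deg[2],
                       cfg$rotation_deg[3])
  rotated <- any(cfg$rotation_deg != 0)
  labs <- NULL
  if (cfg$with_masks) {
    labs <- if (rotated) {
      src <- sweep(sweep(pts, 2, ctr, "-") %*% R, 2, ctr, "+")
      phantom_tissues(src, bc, B, cfg)                  # analytic ground truth
    } else labs_un
  }

  set.seed(cfg$seed)
  tex <- NULL
  if (cfg$texture_sd > 0) {
    tex <- texture_field(proto, cfg$texture_sd, cfg$texture_corr_mm)
    tissue <- labs_un$code %in% PHANTOM_CODES[c("gray", "white")]
    tex[!tissue] <- 0
    tex <- array(tex, d)
  }
  out <- list(config = cfg)
  modalities <- if (cfg$modality == "mr") c("t1", "t2", "pd") else cfg$modality
  first <- TRUE
  for (m in modalities) {
    lut <- phantom_lut(m)
    ivals <- phantom_intensity(labs_un, cfg, lut)
    voln <- vol_like(proto, array(ivals, d))
    if (!is.null(tex)) voln$data <- voln$data + tex
    if (cfg$psf_mm > 0)
      voln$data <- gauss_smooth_3d(voln$data, cfg$psf_mm / cfg$spacing_mm)
    if (rotated) voln <- rotate_volume(voln, R, fill = lut[["air"]])
    img <- voln$data
    if (cfg$inhomogeneity_pct > 0)
      img <- img * bias_field(proto, cfg$inhomogeneity_pct, cfg$seed)
    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), d)
    voln <- vol_like(proto, img)
    if (!is.null(cfg$slice_thickness_mm))
      voln <- resample_slices(voln, cfg$slice_thickness_mm)
    if (first) { out$volume <- voln; first <- FALSE } else out[[m]] <- voln
  }
  grid_out <- out$volume
  if (cfg$with_masks) {
  relab <- function(codes) {
    mk <- array(as.integer(labs$code %in% codes), d)
    v <- vol_like(proto, mk)
    if (!is.null(cfg$slice_thickness_mm)) {
      v <- resample_slices(v, cfg$slice_thickness_mm)
      v$data <- array(as.integer(v$data >= 0.5), dim(v$data))
    }
    v
  }
  out$tissue_labels <- {
    v <- vol_like(proto, array(labs$code, d))
    if (!is.null(cfg$slice_thickness_mm)) v <- resample_onto(v, grid_out, nearest = TRUE)
    v
  }
  out$ventricle_mask <- relab(PHANTOM_CODES["ventricle"])
  out$lesion_mask <- relab(PHANTOM_CODES["lesion"])
  # brain mask = the brain ellipsoid (subarachnoid CSF excluded)
  bm <- vol_like(proto, array(as.integer(labs$inside_brain), d))
  if (!is.null(cfg$slice_thickness_mm)) {
    bm <- resample_slices(bm, cfg$slice_thickness_mm)
    bm$data <- array(as.integer(bm$data >= 0.5), dim(bm$data))
  }
  out$brain_mask <- bm
  }

  msp0 <- plane3d(c(1, 0, 0), bc[1])
  out$truth_msp <- if (rotated) rotate_plane(msp0, R, ctr) else msp0
  out$truth_rotation <- list(R = R, center = ctr, angles_deg = cfg$rotation_deg)
  out$truth_landmarks <- phantom_truth_landmarks(bc, B)
  class(out) <- "phantom_case"
  out
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> modality %s, rotation (%s) deg, %d lesion(s)\n",
              x$config$modality,
              paste(x$config$rotation_deg, collapse = ", "),
              length(x$config$lesion_specs)))
  print(x$volume)
  invisible(x)
}

# evaluate tissue membership at world points (unrotated frame)
phantom_tissues <- function(pts, bc, B, cfg) {
  px <- pts[, 1] - bc[1]; py <- pts[, 2] - bc[2]; pz <- pts[, 3] - bc[3]
  e <- (px / B[1])^2 + (py / B[2])^2 + (pz / B[3])^2
  esq <- function(s) (px / (B[1] + s))^2 + (py / (B[2] + s))^2 +
                     (pz / (B[3] + s))^2
  inside_brain <- e < 1
  code <- integer(length(px))                       # air
  if (cfg$skull) {
    shell <- esq(10) < 1 & esq(4) >= 1
    code[shell] <- PHANTOM_CODES["skull"]
    gap <- esq(4) < 1 & e >= 1
    code[gap] <- PHANTOM_CODES["csf"]
  }
  code[inside_brain] <- PHANTOM_CODES["gray"]
  white <- (px / (0.72 * B[1]))^2 + (py / (0.78 * B[2]))^2 +
           (pz / (0.72 * B[3]))^2 < 1
  code[white] <- PHANTOM_CODES["white"]
  # interhemispheric fissure: thin midline CSF sheet separating the
  # hemispheres, bridged by a corpus-callosum white-matter patch. The width
  # undulates (as real fissures do) via a deterministic smooth function, so
  # the fissure walls are not a flat plane; the midline stays exactly x = 0.
  wfis <- 1.6 + 0.8 * sin(2 * pi * py / 37 + 1.3) * cos(2 * pi * pz / 29)
  h <- cfg$spacing_mm[1]
  cc <- (py / (0.45 * B[2]))^2 + ((pz - 0.15 * B[3]) / (0.22 * B[3]))^2 < 1
  # partial-volume coverage fractions for the two thin midline sheets, so
  # they render correctly at any voxel size (a pure centre-membership test
  # would miss them entirely on coarse grids)
  ffis <- pmin(1, pmax(0, (wfis - abs(px)) / h + 0.5))
  ffis[e >= 0.985 | cc] <- 0
  ffalx <- pmin(1, pmax(0, (0.8 - abs(px)) / h + 0.5))
  ffalx[e >= 0.97 | pz <= -0.2 * B[3] | cc] <- 0
  fis <- ffis > 0.5
  code[fis] <- PHANTOM_CODES["csf"]
  code[ffalx > 0.5] <- PHANTOM_CODES["falx"]
  code[fis & cc] <- PHANTOM_CODES["white"]
  # paired lateral ventricles
  for (s in c(-1, 1)) {
    vent <- ((px - s * 11) / 6.5)^2 + ((py - 2) / 24)^2 + ((pz - 4) / 10)^2 < 1
    code[vent] <- PHANTOM_CODES["ventricle"]
  }
  lesion_id <- integer(length(px))
  for (i in seq_along(cfg$lesion_specs)) {
    ls <- cfg$lesion_specs[[i]]
    lc <- ls$center_mm
    les <- (px - lc[1])^2 + (py - lc[2])^2 + (pz - lc[3])^2 <= ls$radius_mm^2
    les <- les & inside_brain
    code[les] <- PHANTOM_CODES["lesion"]
    lesion_id[les] <- i
    ffis[les] <- 0
    ffalx[les] <- 0
  }
  list(code = code, inside_brain = inside_brain, lesion_id = lesion_id,
       ffis = ffis, ffalx = ffalx)
}

phantom_intensity <- function(labs, cfg, lut) {
  # solid tissues from the label codes; the thin midline sheets are blended
  # in by their analytic partial-volume fractions
  solid <- labs$code
  sheet <- solid %in% PHANTOM_CODES[c("csf", "falx")] & labs$ffis > 0
  solid[sheet & labs$inside_brain] <- PHANTOM_CODES["gray"]
  base <- c(lut[["air"]], lut[["csf"]], lut[["gray"]], lut[["white"]],
            lut[["csf"]], lut[["skull"]], NA, lut[["falx"]])[solid + 1L]
  base[is.na(base)] <- lut[["air"]]
  f <- pmax(0, labs$ffis - labs$ffalx)
  base <- base * (1 - f) + lut[["csf"]] * f
  base <- base * (1 - labs$ffalx) + lut[["falx"]] * labs$ffalx
  for (i in seq_along(cfg$lesion_specs)) {
    ls <- cfg$lesion_specs[[i]]
    val <- switch(ls$contrast, hypodense = lut[["hypo"]],
                  hyperdense = lut[["hyper"]], wmh = lut[["wmh"]])
    base[labs$lesion_id == i] <- val
  }
  base
}

# smooth random texture field, exactly mirror-symmetric about the grid's
# sagittal midplane (correlated Gaussian field, rescaled to the target SD).
# The residual fine-scale component of the smoothed white noise matters: it
# populates the intermediate intensity bins that partial-volume mixtures
# fall into, so the field must be generated at full grid resolution.
texture_field <- function(proto, sd_target, corr_mm) {
  d <- dim(proto$data)
  g <- array(stats::rnorm(prod(d)), d)
  g <- gauss_smooth_3d(g, corr_mm / proto$spacing / 2)
  g <- (g + g[d[1]:1, , ]) / 2               # symmetrize about the midplane
  g * (sd_target / stats::sd(g))
}

# low-order polynomial multiplicative bias field with the stated
# peak-to-peak percentage, deterministic in the seed
bias_field <- function(proto, pct, seed) {
  d <- dim(proto$data)
  ax <- lapply(vol_axes(proto), function(a) (a - mean(a)) / max(abs(a - mean(a))))
  set.seed(seed + 7L)
  cf <- stats::runif(6, -1, 1)
  x <- rep(ax[[1]], times = d[2] * d[3])
  y <- rep(rep(ax[[2]], each = d[1]), times = d[3])
  z <- rep(ax[[3]], each = d[1] * d[2])
  g <- cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y +
       cf[5] * y * z + cf[6] * (x^2 - z^2)
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - mean(rng)) / diff(rng) else g * 0  # [-0.5, 0.5]
  array(1 + g * pct / 100, d)
}

# truth landmarks via the same fractional-ellipse construction used by the
# ellipse mapping path (the phantom has no anatomic AC/PC)
phantom_truth_landmarks <- function(bc, B) {
  f <- ellipse_landmark_fractions()
  ac <- c(bc[1], bc[2] + f$ac_major * B[2], bc[3] + f$ac_minor * B[3])
  pc <- c(bc[1], bc[2] + f$pc_major * B[2], bc[3] + f$pc_minor * B[3])
  landmark_set(AC = ac, PC = pc,
               L = bc[1] - B[1], R = bc[1] + B[1],
               A = bc[2] + B[2], P = bc[2] - B[2],
               S = bc[3] + B[3], I = bc[3] - B[3],
               CC_top = bc[3] + f$cc_minor * B[3],
               OF_ventral = bc[3] + f$of_minor * B[3])
}
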