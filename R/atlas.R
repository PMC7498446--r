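#' Atlas bundle: co-registered anatomy and territory label volumes
#'
#' @param anatomy,territories integer-label `vol3d` volumes on the same grid.
#' @param ventricle_template binary `vol3d` on the same grid.
#' @param legend data frame with columns `code`, `name`, `laterality`
#'   (left/right/midline) and `mirror_code` (code of the mirror-image label;
#'   equal to `code` for midline labels).
#' @param space list describing the normalized space (grid shape/spacing/
#'   origin and its [landmark_set()]).
#' @return object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(anatomy, territories, ventricle_template, legend, space) {
  stopifnot_vol(anatomy, "anatomy"); stopifnot_vol(territories, "territories")
  stopifnot_vol(ventricle_template, "ventricle_template")
  if (!same_grid(anatomy, territories) || !same_grid(anatomy, ventricle_template))
    stop("anatomy, territories and ventricle template must share one grid")
  req <- c("code", "name", "laterality", "mirror_code")
  if (!all(req %in% names(legend))) stop("legend must have columns ",
                                         paste(req, collapse = ", "))
  if (anyDuplicated(legend$code)) stop("legend codes must be unique")
  lat <- legend$laterality %in% c("left", "right")
  if (any(lat & (is.na(legend$mirror_code) |
                 !(legend$mirror_code %in% legend$code))))
    stop("every lateralized label needs a valid mirror_code")
  structure(list(anatomy = anatomy, territories = territories,
                 ventricle_template = ventricle_template,
                 legend = legend, space = space), class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %s grid, %d legend entries\n",
              paste(dim(x$anatomy$data), collapse = "x"), nrow(x$legend)))
  invisible(x)
}

# label code layout: anatomy 10p + side, territories 100 + 10p + side
# side: 1 = left, 2 = right
ANATOMY_PARCELS <- c(frontal = 1L, parietal = 2L, temporal = 3L, occipital = 4L,
                     deep_gray = 5L, white_matter = 6L, ventricle = 7L,
                     brainstem_cerebellum = 8L)
TERRITORY_PARCELS <- c(ACA = 1L, MCA_terminal = 2L, MCA_penetrating = 3L,
                       PCA = 4L)

#' Build the simplified anatomy and blood-supply-territory atlases
#'
#' Procedural atlases in the normalized space: per hemisphere eight anatomy
#' parcels (frontal/parietal/temporal/occipital blocks, deep gray matter,
#' white matter, ventricle, brainstem-cerebellum block) and four arterial
#' territories (ACA, MCA terminal branches, MCA penetrating branches, PCA).
#' Parcel boundaries are planar or ellipsoidal and depend on |x| only, so
#' every left label is the exact mirror image of its right partner; every
#' brain voxel carries exactly one anatomy and one territory label.
#'
#' @param resolution_mm isotropic voxel size of the normalized grid
#'   (default 2 mm; the grid extents stay fixed).
#' @return an [atlas_bundle()].
#' @export
build_simplified_atlas <- function(resolution_mm = 2) {
  if (resolution_mm <= 0) stop("resolution must be positive")
  sp <- atlas_space()
  if (resolution_mm != sp$spacing[1]) {
    ext <- sp$shape * sp$spacing
    ctr0 <- sp$origin + (sp$shape - 1) / 2 * sp$spacing
    shape <- as.integer(round(ext / resolution_mm))
    shape <- shape + (shape %% 2L)            # even: no voxel on x = 0
    sp$shape <- shape
    sp$spacing <- rep(resolution_mm, 3)
    sp$origin <- ctr0 - (shape - 1) / 2 * resolution_mm
  }
  proto <- vol3d(array(0L, sp$shape), sp$spacing, sp$origin)
  pts <- grid_points(proto)
  bc <- sp$brain_center; B <- sp$brain_semi
  px <- pts[, 1] - bc[1]; py <- pts[, 2] - bc[2]; pz <- pts[, 3] - bc[3]
  brain <- (px / B[1])^2 + (py / B[2])^2 + (pz / B[3])^2 < 1
  side <- ifelse(px < 0, 1L, 2L)
  axp <- abs(px)
  # world-frame references (AC at origin)
  wy <- pts[, 2]; wz <- pts[, 3]

  # ventricle geometry proportional to the phantom's (fractions of the brain
  # semi-axes), so individualized templates land on phantom ventricles
  vent <- ((axp - 12.5) / 7.5)^2 + ((wy + 14) / 27.5)^2 + ((wz - 19) / 11)^2 < 1
  deep <- ((axp - 22) / 14)^2 + ((wy + 6) / 20)^2 + ((wz - 2) / 14)^2 < 1 & !vent
  stem <- wz < -18 & wy < -20
  white <- (px / (0.7 * B[1]))^2 + (py / (0.72 * B[2]))^2 +
           (pz / (0.7 * B[3]))^2 < 1
  anat <- integer(length(px))
  a <- function(parcel, sel) {
    code <- 10L * ANATOMY_PARCELS[[parcel]] + side
    anat[brain & sel & anat == 0L] <<- code[brain & sel & anat == 0L]
  }
  a("ventricle", vent)
  a("deep_gray", deep)
  a("brainstem_cerebellum", stem)
  a("white_matter", white)
  a("frontal", wy > 16)
  a("occipital", wy < -64)
  a("parietal", wz > 28)
  a("temporal", rep(TRUE, length(px)))

  terr <- integer(length(px))
  t2 <- function(parcel, sel) {
    code <- 100L + 10L * TERRITORY_PARCELS[[parcel]] + side
    terr[brain & sel & terr == 0L] <<- code[brain & sel & terr == 0L]
  }
  t2("PCA", wy < -64 | (wz < -14 & wy < -8))
  t2("ACA", axp < 15 & wy > -28 & wz > -6)
  t2("MCA_penetrating", deep | vent)
  t2("MCA_terminal", rep(TRUE, length(px)))

  legend <- atlas_legend()
  atlas_bundle(vol_like(proto, array(anat, sp$shape)),
               vol_like(proto, array(terr, sp$shape)),
               vol_like(proto, array(as.integer(vent & brain), sp$shape)),
               legend, sp)
}

atlas_legend <- function() {
  rows <- list()
  add <- function(code, name, lat, mirror)
    rows[[length(rows) + 1L]] <<- data.frame(code = code, name = name,
                                             laterality = lat,
                                             mirror_code = mirror)
  for (p in names(ANATOMY_PARCELS)) {
    b <- 10L * ANATOMY_PARCELS[[p]]
    add(b + 1L, paste("left", gsub("_", " ", p)), "left", b + 2L)
    add(b + 2L, paste("right", gsub("_", " ", p)), "right", b + 1L)
  }
  for (p in names(TERRITORY_PARCELS)) {
    b <- 100L + 10L * TERRITORY_PARCELS[[p]]
    add(b + 1L, paste("left", gsub("_", " ", p)), "left", b + 2L)
    add(b + 2L, paste("right", gsub("_", " ", p)), "right", b + 1L)
  }
  do.call(rbind, rows)
}

#' Write / read an atlas bundle
#'
#' Label volumes go to NIfTI-1 files, the legend and space description to a
#' JSON sidecar. The write/read round trip is the identity on labels and
#' legend.
#'
#' @param bundle an [atlas_bundle()].
#' @param dir output directory (created if missing).
#' @return `write_atlas` the directory; `read_atlas` an [atlas_bundle()].
#' @export
write_atlas <- function(bundle, dir) {
  if (!inherits(bundle, "atlas_bundle")) stop("`bundle` must be an atlas_bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$anatomy, file.path(dir, "anatomy.nii.gz"))
  write_volume(bundle$territories, file.path(dir, "territories.nii.gz"))
  write_volume(bundle$ventricle_template, file.path(dir, "ventricles.nii.gz"))
  meta <- list(legend = bundle$legend,
               space = list(shape = bundle$space$shape,
                            spacing = bundle$space$spacing,
                            origin = bundle$space$origin,
                            brain_center = bundle$space$brain_center,
                            brain_semi = bundle$space$brain_semi,
                            landmarks = unclass(bundle$space$landmarks)))
  jsonlite::write_json(meta, file.path(dir, "legend.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  anatomy <- read_volume(file.path(dir, "anatomy.nii.gz"))
  territories <- read_volume(file.path(dir, "territories.nii.gz"))
  ventricles <- read_volume(file.path(dir, "ventricles.nii.gz"))
  for (v in list(anatomy, territories, ventricles)) {
    if (!same_grid(anatomy, v))
      stop("grid mismatch between atlas volumes (shape or spacing)")
  }
  meta <- jsonlite::read_json(file.path(dir, "legend.json"),
                              simplifyVector = TRUE)
  lm <- meta$space$landmarks
  space <- list(shape = as.integer(meta$space$shape),
                spacing = as.numeric(meta$space$spacing),
                origin = as.numeric(meta$space$origin),
                brain_center = as.numeric(meta$space$brain_center),
                brain_semi = as.numeric(meta$space$brain_semi),
                landmarks = landmark_set(lm$AC, lm$PC, lm$L, lm$R, lm$A, lm$P,
                                         lm$S, lm$I, lm$CC_top, lm$OF_ventral))
  int_vol <- function(v) vol_like(v, array(as.integer(round(v$data)), dim(v$data)))
  atlas_bundle(int_vol(anatomy), int_vol(territories), int_vol(ventricles),
               meta$legend, space)
}

#' Mirror-image mask of a label about the normalized midsagittal plane
#'
#' Exact voxel mirroring about x = 0 (the atlas grid has no x = 0 voxel, so
#' the flip is an index reversal).
#'
#' @param labels label `vol3d` in atlas space.
#' @param code label code.
#' @return logical array, the mirrored mask of `code`.
#' @export
mirror_label_mask <- function(labels, code) {
  m <- labels$data == code
  m[dim(m)[1]:1, , ]
}
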