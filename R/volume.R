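#' 3D intensity volume
#'
#' The universal scan/map carrier: a 3D array of scalar intensities with
#' per-axis voxel spacing (mm) and a world-space origin. World axes are
#' right/anterior/superior (RAS): the first array index increases towards the
#' patient's right, the second towards anterior, the third towards superior.
#' The world coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric or integer array.
#' @param spacing numeric(3), voxel size in mm per axis (all > 0).
#' @param origin numeric(3), world coordinate (mm) of voxel (1, 1, 1).
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

vol_like <- function(v, data) vol3d(data, v$spacing, v$origin)

is_vol3d <- function(x) inherits(x, "vol3d")

stopifnot_vol <- function(v, what = "volume") {
  if (!is_vol3d(v)) stop(sprintf("`%s` must be a vol3d object", what))
  invisible(v)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Per-axis world coordinates of voxel centres
#' @param v a `vol3d`.
#' @return list of three numeric vectors (x, y, z in mm).
#' @export
vol_axes <- function(v) {
  d <- dim(v$data)
  lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 1) * v$spacing[a])
}

#' World coordinate of the grid centre (mm)
#' @param v a `vol3d`.
#' @export
vol_center <- function(v) v$origin + (dim(v$data) - 1) / 2 * v$spacing

# world (n x 3, mm) -> continuous 1-based voxel index (n x 3)
world_to_index <- function(v, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/") + 1
}

index_to_world <- function(v, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

# voxel volume in ml
voxel_ml <- function(v) prod(v$spacing) / 1000

#' Sample a volume at arbitrary world points (trilinear)
#'
#' @param v a `vol3d`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param outside value assigned to points outside the grid (default `NA`).
#' @return numeric vector of length n.
#' @export
sample_trilinear <- function(v, pts, outside = NA_real_) {
  d <- dim(v$data)
  idx <- world_to_index(v, pts)
  i0 <- floor(idx)
  f <- idx - i0
  inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
         idx[, 2] >= 1 & idx[, 2] <= d[2] &
         idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(idx))
  if (!any(inb)) return(out)
  i0 <- i0[inb, , drop = FALSE]; f <- f[inb, , drop = FALSE]
  # clamp so that i0+1 stays in range on the upper boundary
  for (a in 1:3) {
    hi <- i0[, a] >= d[a]
    i0[hi, a] <- d[a] - 1L
    f[hi, a] <- 1
  }
  dat <- v$data
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (i0[, 1]) + (i0[, 2] - 1) * n1 + (i0[, 3] - 1) * n12
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  g <- function(di, dj, dk) dat[base + di + dj * n1 + dk * n12]
  val <-
    g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    g(1, 1, 0) * fx       * fy       * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 0, 1) * fx       * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy       * fz +
    g(1, 1, 1) * fx       * fy       * fz
  out[inb] <- val
  out
}

#' Sample a volume at arbitrary world points (nearest neighbour)
#'
#' Used for label volumes where interpolation is meaningless.
#' @inheritParams sample_trilinear
#' @return vector of length n (same storage mode as the data).
#' @export
sample_nearest <- function(v, pts, outside = 0) {
  d <- dim(v$data)
  idx <- round(world_to_index(v, pts))
  inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
         idx[, 2] >= 1 & idx[, 2] <= d[2] &
         idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(idx))
  if (any(inb)) {
    ii <- idx[inb, , drop = FALSE]
    out[inb] <- v$data[cbind(ii[, 1], ii[, 2], ii[, 3])]
  }
  out
}

# full grid of world coordinates as an n x 3 matrix (column-major voxel order)
grid_points <- function(v) {
  ax <- vol_axes(v)
  d <- dim(v$data)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' Rigidly rotate a volume about its grid centre
#'
#' Resamples with trilinear interpolation: the value at output voxel p is the
#' input sampled at `center + t(R) %*% (p - center)`, i.e. the object is
#' rotated by `R`.
#'
#' @param v a `vol3d`.
#' @param R 3 x 3 rotation matrix (see [rotation_matrix()]).
#' @param fill value for points mapped outside the input grid.
#' @param center rotation centre in world mm (default grid centre).
#' @param nearest use nearest-neighbour sampling (for label/mask volumes).
#' @return a `vol3d` on the same grid.
#' @export
rotate_volume <- function(v, R, fill = 0, center = vol_center(v),
                          nearest = FALSE) {
  pts <- grid_points(v)
  src <- sweep(sweep(pts, 2, center, "-") %*% R, 2, center, "+")
  val <- if (nearest) sample_nearest(v, src, outside = fill)
         else sample_trilinear(v, src, outside = fill)
  vol_like(v, array(val, dim(v$data)))
}

#' Mirror a volume across a plane
#'
#' @param v a `vol3d`.
#' @param plane a `plane3d` (see [plane3d()]).
#' @param fill outside fill value.
#' @param nearest nearest-neighbour sampling for masks/labels.
#' @return reflected `vol3d` on the same grid.
#' @export
mirror_volume <- function(v, plane, fill = 0, nearest = FALSE) {
  pts <- grid_points(v)
  sd <- as.vector(pts %*% plane$normal) - plane$offset
  src <- pts - 2 * sd %*% t(plane$normal)
  val <- if (nearest) sample_nearest(v, src, outside = fill)
         else sample_trilinear(v, src, outside = fill)
  vol_like(v, array(val, dim(v$data)))
}

# resample v onto the grid of `target` (both vol3d), linear or nearest
resample_onto <- function(v, target, fill = 0, nearest = FALSE) {
  if (same_grid(v, target)) return(vol_like(target, v$data))
  pts <- grid_points(target)
  val <- if (nearest) sample_nearest(v, pts, outside = fill)
         else sample_trilinear(v, pts, outside = fill)
  vol_like(target, array(val, dim(target$data)))
}

#' Resample a volume to a coarser slice thickness along z
#'
#' Emulates thick-slice acquisition: each output slice is the mean of the
#' input slices falling in its slab (partial-volume averaging).
#'
#' @param v a `vol3d`.
#' @param thickness_mm output slice thickness (>= z spacing).
#' @return a `vol3d` with coarser z spacing.
#' @export
resample_slices <- function(v, thickness_mm) {
  if (thickness_mm <= v$spacing[3]) return(v)
  d <- dim(v$data)
  zw <- vol_axes(v)[[3]]
  nz <- max(1L, floor((zw[d[3]] - zw[1] + v$spacing[3]) / thickness_mm))
  z0 <- zw[1] + (seq_len(nz) - 0.5) * thickness_mm - v$spacing[3] / 2
  out <- array(0, c(d[1], d[2], nz))
  for (k in seq_len(nz)) {
    lo <- zw[1] + (k - 1) * thickness_mm
    sel <- which(zw >= lo - 1e-9 & zw < lo + thickness_mm - 1e-9)
    out[, , k] <- if (length(sel) > 1)
      rowMeans(matrix(v$data[, , sel], d[1] * d[2]), na.rm = TRUE)
    else v$data[, , sel]
  }
  vol3d(out, c(v$spacing[1:2], thickness_mm),
        c(v$origin[1:2], zw[1] + (thickness_mm - v$spacing[3]) / 2))
}

#' Rotation matrix from yaw / pitch / roll (degrees)
#'
#' Yaw rotates about the superior (z) axis, pitch about the left-right (x)
#' axis, roll about the anterior (y) axis; composition `Rz(yaw) %*% Rx(pitch)
#' %*% Ry(roll)`, applied to column vectors in RAS world coordinates.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(yaw = 0, pitch = 0, roll = 0) {
  d2r <- pi / 180
  cy <- cos(yaw * d2r);   sy <- sin(yaw * d2r)
  cp <- cos(pitch * d2r); sp <- sin(pitch * d2r)
  cr <- cos(roll * d2r);  sr <- sin(roll * d2r)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  Ry <- matrix(c(cr, 0, -sr, 0, 1, 0, sr, 0, cr), 3, 3)
  Rz %*% Rx %*% Ry
}
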