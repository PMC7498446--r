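#' Maximum-intensity-projection slab around the midsagittal plane
#'
#' Resamples a sagittal slab perpendicular to the MSP and takes the per-pixel
#' maximum across the slab, exposing the cortex outline irrespective of the
#' interhemispheric fissure width.
#'
#' @param volume a `vol3d`.
#' @param msp a `plane3d` (near-sagittal).
#' @param width_mm slab thickness (> 0); a width up to one voxel degenerates
#'   to the resampled MSP slice.
#' @return object of class `mip_image`: `image` (matrix, u along rows),
#'   `u`, `v` (plane coordinates, mm) and `frame` (plane origin and in-plane
#'   basis vectors in world coordinates).
#' @export
mip_slab <- function(volume, msp, width_mm = 10) {
  stopifnot_vol(volume)
  if (width_mm <= 0) stop("width_mm must be > 0")
  n <- msp$normal
  ey <- c(0, 1, 0) - sum(c(0, 1, 0) * n) * n
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(0, 0, 1) - sum(c(0, 0, 1) * n) * n - sum(c(0, 0, 1) * ey) * ey
  ez <- ez / sqrt(sum(ez^2))
  ctr <- vol_center(volume)
  p0 <- ctr - (sum(ctr * n) - msp$offset) * n       # plane point nearest centre
  ax <- vol_axes(volume)
  uext <- (ax[[2]][length(ax[[2]])] - ax[[2]][1]) / 2
  vext <- (ax[[3]][length(ax[[3]])] - ax[[3]][1]) / 2
  du <- volume$spacing[2]; dv <- volume$spacing[3]
  u <- seq(-uext, uext, by = du)
  v <- seq(-vext, vext, by = dv)
  tt <- if (width_mm <= min(volume$spacing)) 0
        else seq(-width_mm / 2, width_mm / 2, by = min(volume$spacing))
  uu <- rep(u, times = length(v))
  vv <- rep(v, each = length(u))
  img <- matrix(-Inf, length(u), length(v))
  any_in <- FALSE
  for (t1 in tt) {
    pts <- cbind(p0[1] + uu * ey[1] + vv * ez[1] + t1 * n[1],
                 p0[2] + uu * ey[2] + vv * ez[2] + t1 * n[2],
                 p0[3] + uu * ey[3] + vv * ez[3] + t1 * n[3])
    s <- sample_trilinear(volume, pts)
    any_in <- any_in || any(!is.na(s))
    s[is.na(s)] <- -Inf
    img <- pmax(img, matrix(s, length(u), length(v)))
  }
  if (!any_in) stop("slab lies outside the volume")
  img[!is.finite(img)] <- NA
  structure(list(image = img, u = u, v = v,
                 frame = list(origin = p0, eu = ey, ev = ez, normal = n)),
            class = "mip_image")
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image> %d x %d px, %.1f x %.1f mm\n",
              length(x$u), length(x$v), diff(range(x$u)), diff(range(x$v))))
  invisible(x)
}

#' Fiducial points on the cortex outline of a MIP slice
#'
#' Thresholds the MIP, removes the skull ring (bright shell) if present,
#' keeps the largest connected component, and traces its boundary at subpixel
#' accuracy; the boundary is resampled to evenly spaced fiducials.
#'
#' @param mip a `mip_image` from [mip_slab()].
#' @param threshold foreground threshold (default: Otsu).
#' @param n_fiducials number of boundary points returned (>= 64).
#' @return n x 2 matrix of (u, v) plane coordinates in mm, with the `frame`
#'   attribute copied from the input for 3D reconstruction.
#' @export
cortex_outline <- function(mip, threshold = NULL, n_fiducials = 128L) {
  if (!inherits(mip, "mip_image")) stop("`mip` must be a mip_image")
  n_fiducials <- max(64L, as.integer(n_fiducials))
  img <- mip$image
  vals <- img[is.finite(img)]
  if (!length(vals) || diff(range(vals)) < 1e-9)
    stop("empty image: no component above threshold")
  # skull shell shows up as a very bright rim: exclude the top intensity tail
  # when it is well separated from the tissue bulk
  bgt <- background_threshold(vals)
  fgv <- vals[vals > bgt]
  skull_cut <- Inf
  q <- stats::quantile(fgv, c(0.5, 0.995), names = FALSE)
  if (q[2] > 1.6 * q[1]) skull_cut <- 0.5 * (q[1] + q[2])
  if (is.null(threshold)) {
    # two-stage: drop the air background and the skull rim, then split CSF
    # from tissue, so the contour level sits on the cortex/CSF edge
    threshold <- otsu_threshold(fgv[fgv < skull_cut])
  }
  fg <- !is.na(img) & img > threshold & img < skull_cut
  if (!any(fg) && threshold >= max(fgv)) {
    # degenerate (binary-like) image: fall back to the background split
    threshold <- 0.5 * (bgt + threshold)
    fg <- !is.na(img) & img > threshold & img < skull_cut
  }
  if (!any(fg)) stop("no component above threshold")
  lab <- label_components(fg)
  main <- which.max(tabulate(lab[lab > 0L]))
  comp <- fill_holes_2d(lab == main)
  work <- img
  work[is.na(work)] <- 0
  # keep a halo of original intensities around the component so the contour
  # can interpolate along the true boundary ramp (zeroing at the threshold
  # crossing itself would bias the outline inwards)
  halo <- comp
  for (k in 1:2) for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    halo <- halo | arr_shift(halo, dd, FALSE)
  work[!halo] <- 0
  work[halo & img >= skull_cut] <- 0
  work[comp & img >= skull_cut] <- stats::median(vals[fg])
  # contour at the fg threshold itself: it sits midway between the tissue
  # and surround intensities, so the subpixel boundary is unbiased
  lev <- min(threshold, 0.95 * stats::median(work[comp]))
  cl <- grDevices::contourLines(x = mip$u, y = mip$v, z = work, levels = lev)
  if (!length(cl)) stop("no component above threshold")
  lens <- vapply(cl, function(c1) length(c1$x), 1L)
  bnd <- cl[[which.max(lens)]]
  pts <- cbind(bnd$x, bnd$y)
  # arc-length resampling to evenly spaced fiducials
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], length.out = n_fiducials + 1L)[-(n_fiducials + 1L)]
  fid <- cbind(stats::approx(s, pts[, 1], si)$y, stats::approx(s, pts[, 2], si)$y)
  attr(fid, "frame") <- mip$frame
  fid
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `ax^2 + bxy + cy^2 + dx + ey + f = 0` under the ellipse
#' constraint `4ac - b^2 = 1` (direct constrained least squares), returning
#' geometric parameters.
#'
#' @param points n x 2 matrix (n >= 6, not collinear).
#' @return object of class `ellipse_fit`: `center` (2), `a` (semi-major),
#'   `b` (semi-minor), `orientation` (radians, major axis vs +x, in
#'   (-pi/2, pi/2]), `rms` (RMS orthogonal-ish residual, mm).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 6L) stop("need at least 6 points")
  mu <- colMeans(pts); sc <- max(stats::sd(pts[, 1]), stats::sd(pts[, 2]))
  if (!is.finite(sc) || sc < 1e-9) stop("degenerate point configuration")
  x <- (pts[, 1] - mu[1]) / sc; y <- (pts[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration"))
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 1e-12)
  if (!length(k)) stop("degenerate point configuration: no ellipse solution")
  a1 <- V[, k[1]]
  coef <- c(a1, as.vector(T1 %*% a1))   # (A, B, C, D, E, F) in scaled frame
  # unscale: x = (X - mux)/sc
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4] * sc - 2 * A * mu[1] - B * mu[2]
  E <- coef[5] * sc - 2 * C * mu[2] - B * mu[1]
  F1 <- coef[6] * sc^2 + A * mu[1]^2 + B * mu[1] * mu[2] + C * mu[2]^2 -
        coef[4] * sc * mu[1] - coef[5] * sc * mu[2]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("degenerate point configuration: not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # centred conic: (p - c)' M (p - c) = -f0 with M the quadratic form
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  f0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F1
  eg <- eigen(M2, symmetric = TRUE)
  semi <- sqrt(-f0 / eg$values)          # eigenvalues sorted decreasing
  if (any(!is.finite(semi))) stop("degenerate point configuration: not an ellipse")
  axes <- sort(semi, decreasing = TRUE)
  vmaj <- eg$vectors[, which.max(semi)]
  theta <- atan2(vmaj[2], vmaj[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  # residual: scaled algebraic distance has gradient ~ 1 near the curve after
  # normalization by the local gradient magnitude (Sampson distance)
  g <- A * pts[, 1]^2 + B * pts[, 1] * pts[, 2] + C * pts[, 2]^2 +
       D * pts[, 1] + E * pts[, 2] + F1
  gx <- 2 * A * pts[, 1] + B * pts[, 2] + D
  gy <- 2 * C * pts[, 2] + B * pts[, 1] + E
  rms <- sqrt(mean((g / pmax(sqrt(gx^2 + gy^2), 1e-12))^2))
  structure(list(center = c(cx, cy), a = axes[1], b = axes[2],
                 orientation = theta, rms = rms), class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> centre (%.2f, %.2f) mm, a %.2f, b %.2f mm, %.2f deg, rms %.3f mm\n",
              x$center[1], x$center[2], x$a, x$b,
              x$orientation * 180 / pi, x$rms))
  invisible(x)
}

#' Statistical landmark placement from the cortex ellipse
#'
#' The AC and PC are placed at fixed fractions of the semi-axes from the
#' ellipse centre; cortical A/P and S/I come from the ellipse extremes; the
#' lateral L/R landmarks must come from the 3D brain mask (the MSP MIP cannot
#' provide them) and are passed in, defaulting to a fixed fraction of the
#' major axis on either side of the plane. Default fractions are calibrated
#' so that the construction reproduces the normalized space's stored
#' landmarks on the atlas ellipse.
#'
#' @param fit an `ellipse_fit` of the MSP cortex outline, in plane (u, v)
#'   coordinates (u towards anterior, v towards superior).
#' @param frame optional plane frame (from [mip_slab()]); when supplied,
#'   landmarks are expressed in world coordinates, otherwise in plane
#'   coordinates with x = 0 on the plane.
#' @param lateral optional c(L, R) world x coordinates from the brain mask.
#' @param fractions placement fractions (see [ellipse_landmark_fractions]).
#' @param extended also place CC_top / OF_ventral.
#' @return a [landmark_set()].
#' @export
landmarks_from_ellipse <- function(fit, frame = NULL, lateral = NULL,
                                   fractions = ellipse_landmark_fractions(),
                                   extended = TRUE) {
  if (!inherits(fit, "ellipse_fit")) stop("`fit` must be an ellipse_fit")
  m <- c(cos(fit$orientation), sin(fit$orientation))
  if (m[1] < 0) m <- -m                      # major axis towards anterior
  nvec <- c(-m[2], m[1])
  if (nvec[2] < 0) nvec <- -nvec             # minor axis towards superior
  at <- function(fm, fn) fit$center + fm * fit$a * m + fn * fit$b * nvec
  f <- fractions
  ac2 <- at(f$ac_major, f$ac_minor)
  pc2 <- at(f$pc_major, f$pc_minor)
  a2 <- at(1, 0); p2 <- at(-1, 0); s2 <- at(0, 1); i2 <- at(0, -1)
  if (is.null(frame)) {
    to3 <- function(uv) c(0, uv[1], uv[2])
  } else {
    to3 <- function(uv) frame$origin + uv[1] * frame$eu + uv[2] * frame$ev
  }
  msp_x <- to3(fit$center)[1]
  if (is.null(lateral)) {
    lr <- if (is.null(f$lr_major)) 68 / 86 else f$lr_major
    lateral <- c(msp_x - lr * fit$a, msp_x + lr * fit$a)
  }
  landmark_set(AC = to3(ac2), PC = to3(pc2),
               L = lateral[1], R = lateral[2],
               A = to3(a2)[2], P = to3(p2)[2],
               S = to3(s2)[3], I = to3(i2)[3],
               CC_top = if (extended) to3(at(0, f$cc_minor))[3] else NULL,
               OF_ventral = if (extended) to3(at(0, f$of_minor))[3] else NULL)
}

#' Piecewise-linear (Talairach-style) transform between landmark sets
#'
#' Subdivides the bounding box into cuboidal regions by the landmark planes
#' (2 lateral x 3 anterior-posterior x 2 vertical = 12 regions; the extended
#' form splits the vertical slabs at the corpus-callosum top and the
#' orbito-frontal floor, giving 4 vertical slabs and 24 regions) and maps
#' each source cuboid onto its target cuboid with per-axis linear scaling.
#' The mapping is separable and continuous across shared boundary planes.
#' Degrees of freedom: 7 scales + 3 translation + 3 orientation = 13 for the
#' 12-region form; 9 scales give 15 for the 24-region form.
#'
#' @param source,target [landmark_set()] objects.
#' @param extended use the 24-region form (requires CC_top / OF_ventral in
#'   both landmark sets).
#' @return object of class `pwl_transform` with `regions` (data frame of
#'   cuboids and scale factors) and `dof`.
#' @export
build_transform <- function(source, target, extended = FALSE) {
  for (lm in list(source, target))
    if (!inherits(lm, "landmark_set")) stop("landmark sets required")
  if (extended && !(has_extended(source) && has_extended(target)))
    stop("extended transform requires CC_top and OF_ventral in both sets")
  bp <- function(lm) {
    zb <- if (extended) c(lm$I, lm$OF_ventral, lm$AC[3], lm$CC_top, lm$S)
          else c(lm$I, lm$AC[3], lm$S)
    list(x = c(lm$L, lm$AC[1], lm$R),
         y = c(lm$P, lm$PC[2], lm$AC[2], lm$A),
         z = zb)
  }
  sb <- bp(source); tb <- bp(target)
  for (axn in c("x", "y", "z")) {
    if (any(diff(sb[[axn]]) <= 0) || any(diff(tb[[axn]]) <= 0))
      stop("landmark ordering violation on axis ", axn)
  }
  nreg <- (length(sb$x) - 1) * (length(sb$y) - 1) * (length(sb$z) - 1)
  regions <- expand.grid(ix = seq_len(length(sb$x) - 1),
                         iy = seq_len(length(sb$y) - 1),
                         iz = seq_len(length(sb$z) - 1))
  regions$sx <- diff(tb$x)[regions$ix] / diff(sb$x)[regions$ix]
  regions$sy <- diff(tb$y)[regions$iy] / diff(sb$y)[regions$iy]
  regions$sz <- diff(tb$z)[regions$iz] / diff(sb$z)[regions$iz]
  regions$x_lo <- sb$x[regions$ix]; regions$x_hi <- sb$x[regions$ix + 1]
  regions$y_lo <- sb$y[regions$iy]; regions$y_hi <- sb$y[regions$iy + 1]
  regions$z_lo <- sb$z[regions$iz]; regions$z_hi <- sb$z[regions$iz + 1]
  dof <- if (extended) 15L else 13L
  structure(list(source = source, target = target, extended = extended,
                 breaks_source = sb, breaks_target = tb,
                 regions = regions, n_regions = nreg, dof = dof),
            class = "pwl_transform")
}

#' @export
print.pwl_transform <- function(x, ...) {
  cat(sprintf("<pwl_transform> %d cuboidal regions, %d degrees of freedom%s\n",
              x$n_regions, x$dof, if (x$extended) " (extended)" else ""))
  invisible(x)
}

#' Apply a piecewise-linear transform to points
#'
#' Points outside the source bounding box are clamped to it (with a warning):
#' robustness matters more than extrapolation fidelity in emergency-room use.
#'
#' @param t a `pwl_transform`.
#' @param points n x 3 matrix of source-space points (mm).
#' @return n x 3 matrix of target-space points.
#' @export
apply_to_points <- function(t, points) {
  if (!inherits(t, "pwl_transform")) stop("`t` must be a pwl_transform")
  pts <- rbind(points)
  out <- pts
  clamped <- FALSE
  for (a in 1:3) {
    sbp <- t$breaks_source[[a]]
    x <- pts[, a]
    if (any(x < sbp[1] | x > sbp[length(sbp)])) clamped <- TRUE
    out[, a] <- pwl_map_axis(t, a, x, extrapolate = FALSE)
  }
  if (clamped) warning("points outside the transform bounding box were clamped")
  out
}

# 1D piecewise-linear landmark mapping; either clamp at the outer landmarks
# or continue linearly with the edge slab's scale (used for label resampling,
# where positions beyond the cortex must map beyond it, not onto it)
pwl_map_axis <- function(t, a, x, extrapolate = TRUE) {
  sbp <- t$breaks_source[[a]]; tbp <- t$breaks_target[[a]]
  n <- length(sbp)
  y <- stats::approx(sbp, tbp, pmin(pmax(x, sbp[1]), sbp[n]),
                     method = "linear", ties = "ordered")$y
  if (extrapolate) {
    lo <- x < sbp[1]; hi <- x > sbp[n]
    if (any(lo)) y[lo] <- tbp[1] +
      (x[lo] - sbp[1]) * (tbp[2] - tbp[1]) / (sbp[2] - sbp[1])
    if (any(hi)) y[hi] <- tbp[n] +
      (x[hi] - sbp[n]) * (tbp[n] - tbp[n - 1]) / (sbp[n] - sbp[n - 1])
  }
  y
}

# extrapolating variant of apply_to_points (no clamping, no warning)
apply_to_points_ext <- function(t, points) {
  pts <- rbind(points)
  out <- pts
  for (a in 1:3) out[, a] <- pwl_map_axis(t, a, pts[, a])
  out
}

#' Invert a piecewise-linear transform
#' @param t a `pwl_transform`.
#' @return the inverse `pwl_transform` (region-by-region exact).
#' @export
invert_transform <- function(t) build_transform(t$target, t$source, t$extended)

#' Resample a label volume through a piecewise-linear transform
#'
#' @param t a `pwl_transform` mapping source space to target space.
#' @param labels integer-label `vol3d` in the source space.
#' @param out_grid a `vol3d` defining the target grid.
#' @return label `vol3d` on `out_grid` (nearest-neighbour).
#' @export
apply_to_labels <- function(t, labels, out_grid) {
  stopifnot_vol(labels, "labels"); stopifnot_vol(out_grid, "out_grid")
  inv <- invert_transform(t)
  pts <- grid_points(out_grid)
  src <- apply_to_points_ext(inv, pts)
  vol_like(out_grid, array(as.integer(sample_nearest(labels, src, outside = 0L)),
                           dim(out_grid$data)))
}

#' Individualize an atlas onto a scan
#'
#' Full ellipse chain: MSP extraction, sagittal MIP slab, cortex outline,
#' ellipse fit, statistical landmark placement, piecewise-linear transform
#' from the atlas space landmarks to the scan landmarks, and nearest-neighbour
#' resampling of the anatomy, territory and ventricle-template volumes onto
#' the scan grid. With `method = "landmarks-given"` the supplied landmarks
#' replace the ellipse stages.
#'
#' @param bundle an [atlas_bundle()].
#' @param scan a `vol3d`.
#' @param method `"ellipse"` or `"landmarks-given"`.
#' @param landmarks scan-space [landmark_set()] for `"landmarks-given"`.
#' @param params list: `slab_mm` (MIP slab width, 10), `extended` (24-region
#'   transform when extended landmarks available, TRUE), `msp` (`"auto"`,
#'   `"kl"` or `"tilted"`), `tilt_align_deg` (reorient the scan before the
#'   ellipse stages when the MSP tilt exceeds this, 2).
#' @return list: `bundle` (individualized atlas on the scan grid),
#'   `transform` (atlas space to aligned scan space), `msp`, `landmarks`,
#'   `ellipse`, `prerotation` (alignment rotation matrix or NULL).
#' @export
individualize_atlas <- function(bundle, scan, method = c("ellipse", "landmarks-given"),
                                landmarks = NULL, params = list()) {
  method <- match.arg(method)
  if (!inherits(bundle, "atlas_bundle")) stop("`bundle` must be an atlas_bundle")
  stopifnot_vol(scan, "scan")
  p <- modifyList(list(slab_mm = 10, extended = TRUE, msp = "auto",
                       tilt_align_deg = 2), params)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("individualize_atlas failed at stage '%s': %s",
                 name, conditionMessage(e)), call. = FALSE))
  Ralign <- NULL
  ctr <- vol_center(scan)
  work <- scan
  if (method == "ellipse") {
    # the base KL extraction is accurate (including the plane offset) up to
    # ~25 degrees of head rotation on the original, unresampled volume; the
    # skull-fit pre-rotation path is reserved for larger tilts, where its
    # extra resampling pass is the lesser evil
    pl <- stage("msp", switch(p$msp,
      kl = extract_msp(scan, p),
      tilted = extract_msp_tilted(scan, p),
      auto = {
        est <- tryCatch(estimate_head_rotation(scan), error = function(e) 0)
        if (max(abs(est)) > 25) extract_msp_tilted(scan, p)
        else extract_msp(scan, p)
      }))
    tilt <- plane_angle(pl, plane3d(c(1, 0, 0), 0))
    if (tilt > p$tilt_align_deg) {
      # rotate so the extracted MSP becomes a grid-aligned sagittal plane;
      # points map as p_aligned = c + t(Ralign) (p - c), so Ralign must take
      # the x axis onto the extracted plane normal
      Ralign <- t(rotation_to_x(pl$normal))
      work <- rotate_volume(scan, t(Ralign), fill = min(scan$data), center = ctr)
      pl <- rotate_plane(pl, t(Ralign), ctr)
    }
    mip <- stage("mip_slab", mip_slab(work, pl, p$slab_mm))
    fid <- stage("cortex_outline", cortex_outline(mip))
    fit <- stage("fit_ellipse", fit_ellipse(fid))
    bm <- stage("brain_mask", scan_brain_mask(work))
    lms0 <- stage("landmarks_from_ellipse",
                  landmarks_from_ellipse(fit, frame = attr(fid, "frame"),
                                         extended = TRUE))
    lat <- stage("lateral_landmarks", lateral_extents(bm, z_mm = lms0$AC[3]))
    lms <- stage("landmarks_from_ellipse",
                 landmarks_from_ellipse(fit, frame = attr(fid, "frame"),
                                        lateral = lat, extended = TRUE))
  } else {
    if (is.null(landmarks)) stop("method 'landmarks-given' requires landmarks")
    lms <- landmarks
    pl <- plane3d(c(1, 0, 0), lms$AC[1])
    fit <- NULL
  }
  ext <- isTRUE(p$extended) && has_extended(lms) &&
         has_extended(bundle$space$landmarks)
  tr <- stage("build_transform",
              build_transform(bundle$space$landmarks, lms, extended = ext))
  inv <- invert_transform(tr)
  pts <- grid_points(scan)
  if (!is.null(Ralign))
    pts <- sweep(sweep(pts, 2, ctr, "-") %*% Ralign, 2, ctr, "+")
  src <- apply_to_points_ext(inv, pts)
  pull <- function(lv) vol_like(scan, array(
    as.integer(sample_nearest(lv, src, outside = 0L)), dim(scan$data)))
  out_bundle <- bundle
  out_bundle$anatomy <- pull(bundle$anatomy)
  out_bundle$territories <- pull(bundle$territories)
  out_bundle$ventricle_template <- pull(bundle$ventricle_template)
  # report the MSP in the scan's own (unaligned) coordinates
  pl_scan <- if (!is.null(Ralign)) rotate_plane(pl, Ralign, ctr) else pl
  list(bundle = out_bundle, transform = tr, msp = pl_scan,
       msp_aligned = pl, landmarks = lms, ellipse = fit,
       prerotation = Ralign)
}

# minimal rotation taking unit vector n to the +x axis
rotation_to_x <- function(n) {
  n <- n / sqrt(sum(n^2))
  x <- c(1, 0, 0)
  v <- crossprod3(n, x)
  s <- sqrt(sum(v^2)); cth <- sum(n * x)
  if (s < 1e-12) return(diag(3) * sign(cth))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# brain mask for landmark support: skull-based CT extraction when a skull
# shell is present, otherwise foreground thresholding
scan_brain_mask <- function(volume) {
  tryCatch(extract_brain_ct(volume), error = function(e) {
    bg <- background_threshold(as.vector(volume$data))
    m <- volume$data > bg
    lab <- label_components(m)
    tb <- tabulate(lab[lab > 0L])
    vol_like(volume, array(as.integer(lab == which.max(tb)), dim(volume$data)))
  })
}

# L/R world x coordinates of the most lateral brain-mask voxels (the
# classical cortical L/R landmarks are the hemispheres' maximal lateral
# extents), with a half-voxel edge correction
lateral_extents <- function(brain_mask, z_mm = NULL) {
  ax <- vol_axes(brain_mask)
  any_x <- apply(brain_mask$data != 0, 1, any)
  if (!any(any_x)) stop("brain mask is empty")
  ix <- range(which(any_x))
  c(ax[[1]][ix[1]] - brain_mask$spacing[1] / 2,
    ax[[1]][ix[2]] + brain_mask$spacing[1] / 2)
}
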