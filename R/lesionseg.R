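#' Multi-modal white-matter-hyperintensity segmentation
#'
#' Simple range thresholding with intersection semantics: a voxel belongs to
#' the WMH mask iff its intensity falls inside the configured range in every
#' one of the three co-registered pulse sequences (WMHs are bright on T2 and
#' PD, iso-to-dark on T1).
#'
#' @param t1,t2,pd co-registered `vol3d` volumes.
#' @param ranges list with elements `t1`, `t2`, `pd`, each `c(lo, hi)`
#'   (inclusive).
#' @param brain_mask optional `vol3d` restricting the search.
#' @return list: `mask` (`vol3d`, 0/1) and `contours` ([contour_set()]).
#' @export
segment_wmh <- function(t1, t2, pd, ranges, brain_mask = NULL) {
  for (v in list(t1, t2, pd)) stopifnot_vol(v)
  if (!same_grid(t1, t2) || !same_grid(t1, pd))
    stop("grid mismatch between pulse sequences")
  need <- c("t1", "t2", "pd")
  if (!all(need %in% names(ranges))) stop("ranges must name t1, t2 and pd")
  m <- t1$data >= ranges$t1[1] & t1$data <= ranges$t1[2] &
       t2$data >= ranges$t2[1] & t2$data <= ranges$t2[2] &
       pd$data >= ranges$pd[1] & pd$data <= ranges$pd[2]
  if (!is.null(brain_mask)) {
    if (!same_grid(t1, brain_mask)) stop("grid mismatch with brain mask")
    m <- m & brain_mask$data != 0
  }
  mask <- vol_like(t1, array(as.integer(m), dim(t1$data)))
  list(mask = mask,
       contours = if (any(m)) contours_from_mask(mask)
                  else contour_set(list(), list(shape = dim(t1$data),
                                                spacing = t1$spacing,
                                                origin = t1$origin)))
}

#' Quantify WMH loci against the ventricular system
#'
#' Connected components (26-connectivity) of the WMH mask are measured for
#' volume, centroid and minimum Euclidean distance to the ventricular
#' surface; a locus is periventricular when that distance does not exceed
#' `periventricular_mm` (the Fazekas-style periventricular/deep split).
#'
#' @param mask WMH `vol3d` (0/1).
#' @param ventricle_mask co-registered ventricular `vol3d` (0/1).
#' @param periventricular_mm distance cut-off in mm (default 10).
#' @return object of class `wmh_report`: `n_loci`, `total_volume_ml` and a
#'   data frame `loci` (volume_ml, centroid, distance, periventricular).
#' @export
quantify_wmh <- function(mask, ventricle_mask, periventricular_mm = 10) {
  stopifnot_vol(mask); stopifnot_vol(ventricle_mask)
  if (!same_grid(mask, ventricle_mask)) stop("grid mismatch between masks")
  lab <- label_components(mask$data != 0)
  n <- max(lab)
  vml <- voxel_ml(mask)
  have_vent <- any(ventricle_mask$data != 0)
  if (!have_vent) warning("empty ventricle mask: distances reported as NA")
  surf <- NULL
  if (have_vent) {
    vm <- ventricle_mask$data != 0
    core <- erode_mask(vm, max(mask$spacing), mask$spacing)
    sv <- vm & !core
    if (!any(sv)) sv <- vm
    idx <- which(sv, arr.ind = TRUE)
    surf <- index_to_world(ventricle_mask, idx)
  }
  rows <- lapply(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    w <- index_to_world(mask, idx)
    dmin <- NA_real_
    if (have_vent) {
      inside <- ventricle_mask$data[idx] != 0
      if (any(inside)) dmin <- 0
      else dmin <- min_pointset_distance(w, surf)
    }
    data.frame(locus = i, volume_ml = nrow(idx) * vml,
               centroid_x = mean(w[, 1]), centroid_y = mean(w[, 2]),
               centroid_z = mean(w[, 3]),
               distance_mm = dmin,
               periventricular = if (is.na(dmin)) NA else dmin <= periventricular_mm)
  })
  loci <- if (n) do.call(rbind, rows) else
    data.frame(locus = integer(), volume_ml = numeric(),
               centroid_x = numeric(), centroid_y = numeric(),
               centroid_z = numeric(), distance_mm = numeric(),
               periventricular = logical())
  structure(list(n_loci = n, total_volume_ml = sum(loci$volume_ml),
                 loci = loci, periventricular_mm = periventricular_mm),
            class = "wmh_report")
}

#' @export
print.wmh_report <- function(x, ...) {
  cat(sprintf("<wmh_report> %d locus/loci, %.2f ml total (periventricular cut-off %g mm)\n",
              x$n_loci, x$total_volume_ml, x$periventricular_mm))
  if (x$n_loci) print(x$loci, row.names = FALSE)
  invisible(x)
}

# chunked exact min distance from each point set to a surface point set
min_pointset_distance <- function(pts, surf) {
  best <- Inf
  step <- 2000L
  for (s in seq(1, nrow(surf), by = step)) {
    blk <- surf[s:min(nrow(surf), s + step - 1L), , drop = FALSE]
    d2 <- outer(rowSums(pts^2), rep(1, nrow(blk))) +
          outer(rep(1, nrow(pts)), rowSums(blk^2)) -
          2 * pts %*% t(blk)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Skull-based brain extraction for CT
#'
#' Thresholds at the lower shoulder of the skull intensity mode, keeps the
#' largest connected tissue component interior to the skull shell and fills
#' internal cavities (ventricles) back in.
#'
#' @param volume CT-style `vol3d` with the skull as the brightest shell.
#' @return binary `vol3d` brain mask.
#' @export
extract_brain_ct <- function(volume) {
  stopifnot_vol(volume)
  vals <- as.vector(volume$data)
  bg <- background_threshold(vals)
  fg <- vals[vals > bg]
  if (length(fg) < 1000) stop("no skull shell found: volume looks empty")
  skull_peak <- stats::quantile(fg, 0.995, names = FALSE)
  tis_med <- stats::median(fg)
  if (skull_peak < 1.6 * tis_med)
    stop("no skull shell found: intensity ceiling too close to tissue")
  skull_lower <- 0.5 * (tis_med + skull_peak)   # lower shoulder of the mode
  csf_cut <- bg + 0.6 * (tis_med - bg)          # drop subarachnoid CSF
  skull <- volume$data > skull_lower
  if (mean(skull) < 0.002) stop("no skull shell found: too few shell voxels")
  # interior of the shell, keeping a margin off its partial-volume inner rim
  inner <- fill_holes(skull) &
    !dilate_mask(skull, 1.5 * max(volume$spacing), volume$spacing)
  band <- inner & volume$data > csf_cut
  lab <- label_components(band)
  if (max(lab) == 0L) stop("no brain component interior to the skull shell")
  main <- which.max(tabulate(lab[lab > 0L]))
  # closing reabsorbs the interhemispheric fissure and the partial-volume rim;
  # hole filling recovers the ventricles
  mask <- lab == main
  r <- 2.2 * max(volume$spacing)
  mask <- erode_mask(dilate_mask(mask, r, volume$spacing), r, volume$spacing)
  mask <- fill_holes(mask)
  vol_like(volume, array(as.integer(mask), dim(volume$data)))
}

#' Remove cerebrospinal fluid from an extracted brain
#'
#' CSF density overlaps infarct density, so CSF voxels are removed before
#' asymmetry analysis. The search is confined to a dilated individualized
#' ventricular template (limiting leakage into hypodense lesions); within the
#' region of interest the CSF/tissue threshold comes from the intensity
#' histogram split (Otsu).
#'
#' @param volume `vol3d` scan.
#' @param brain_mask binary `vol3d`.
#' @param ventricle_template individualized ventricular template (`vol3d`).
#' @param dilate_mm template dilation radius (default 4 mm).
#' @return binary `vol3d`: brain mask minus detected CSF.
#' @export
remove_csf <- function(volume, brain_mask, ventricle_template, dilate_mm = 4) {
  stopifnot_vol(volume); stopifnot_vol(brain_mask); stopifnot_vol(ventricle_template)
  if (!same_grid(volume, brain_mask) || !same_grid(volume, ventricle_template))
    stop("grid mismatch")
  if (!any(ventricle_template$data != 0)) stop("empty ventricular template")
  roi <- ventricle_template$data != 0
  if (dilate_mm > 0) roi <- dilate_mask(roi, dilate_mm, volume$spacing)
  roi <- roi & brain_mask$data != 0
  vals <- volume$data[roi]
  thr <- otsu_threshold(vals)
  # guard: only remove anything if the split is genuinely bimodal (the CSF
  # and tissue means must be well separated relative to their spreads)
  lo <- vals[vals < thr]; hi <- vals[vals >= thr]
  bimodal <- length(lo) > 10 && length(hi) > 10 &&
    (mean(hi) - mean(lo)) > 5 * sqrt((stats::var(lo) + stats::var(hi)) / 2)
  csf <- if (bimodal) roi & volume$data < thr else roi & FALSE
  out <- brain_mask$data != 0 & !csf
  vol_like(volume, array(as.integer(out), dim(volume$data)))
}

#' Segment a diffusion lesion by left/right PDF divergence
#'
#' Builds smoothed intensity probability density functions for the two
#' hemispheres (split by the MSP) on shared bins; intensity bins where the
#' ratio of one side's density to its mirror exceeds `ratio` are flagged, and
#' voxels of the over-represented side falling in flagged bins are marked.
#' The raw mask is cleaned by morphological opening and a minimum component
#' volume.
#'
#' @param volume DWI-style `vol3d`.
#' @param msp the midsagittal [plane3d()].
#' @param params list: `ratio` (bin flag threshold, 3), `nbins` (64),
#'   `eps` (PDF smoothing, 1e-6), `min_ml` (minimum component volume, 1),
#'   `open_mm` (opening radius, one voxel), `brain_mask` (optional `vol3d`).
#' @return list: `mask` (`vol3d` 0/1), `volume_ml`.
#' @export
segment_infarct_dwi <- function(volume, msp, params = list()) {
  stopifnot_vol(volume)
  p <- modifyList(list(ratio = 3, nbins = 64L, eps = 1e-6, min_ml = 1,
                       open_mm = NULL, brain_mask = NULL), params)
  if (is.null(p$open_mm)) p$open_mm <- max(volume$spacing)
  bm <- if (is.null(p$brain_mask)) {
    bg <- background_threshold(as.vector(volume$data))
    volume$data > bg
  } else p$brain_mask$data != 0
  pts <- grid_points(volume)
  sdist <- plane_signed_dist(msp, pts)
  left <- array(sdist < 0, dim(volume$data)) & bm
  right <- array(sdist > 0, dim(volume$data)) & bm
  nl <- sum(left); nr <- sum(right)
  if (abs(log(nl / nr)) > 0.2)
    warning("hemisphere voxel counts differ grossly: the MSP may be wrong")
  vl <- volume$data[left]; vr <- volume$data[right]
  rng <- stats::quantile(c(vl, vr), c(0.001, 0.999), names = FALSE)
  edges <- seq(rng[1], rng[2], length.out = p$nbins + 1L)
  pdf_of <- function(x) {
    cnt <- tabulate(findInterval(x, edges, all.inside = TRUE), p$nbins)
    (cnt / sum(cnt) + p$eps) / (1 + p$nbins * p$eps)
  }
  pl <- pdf_of(vl); pr <- pdf_of(vr)
  flag_l <- pl / pr >= p$ratio
  flag_r <- pr / pl >= p$ratio
  binidx <- array(findInterval(volume$data, edges, all.inside = TRUE),
                  dim(volume$data))
  raw <- (left & array(flag_l[binidx], dim(volume$data))) |
         (right & array(flag_r[binidx], dim(volume$data)))
  if (any(raw)) raw <- open_mask(raw, p$open_mm, volume$spacing)
  if (any(raw)) {
    lab <- label_components(raw)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * voxel_ml(volume) >= p$min_ml)
    raw <- array(lab %in% keep, dim(volume$data))
  }
  mask <- vol_like(volume, array(as.integer(raw), dim(volume$data)))
  list(mask = mask, volume_ml = sum(raw) * voxel_ml(volume))
}
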