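#' Intensity histogram with fixed binning
#'
#' @param bin_edges strictly increasing numeric vector (>= 3 values).
#' @param probabilities nonnegative, summing to 1 (within 1e-9).
#' @return object of class `intensity_histogram`.
#' @export
intensity_histogram <- function(bin_edges, probabilities) {
  bin_edges <- as.numeric(bin_edges); probabilities <- as.numeric(probabilities)
  if (length(bin_edges) < 3L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 bins")
  if (length(probabilities) != length(bin_edges) - 1L)
    stop("need one probability per bin")
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-9)
    stop("probabilities must be nonnegative and sum to 1")
  structure(list(bin_edges = bin_edges, probabilities = probabilities),
            class = "intensity_histogram")
}

# histogram from raw values on fixed edges (values clamped into range)
hist_on_edges <- function(values, edges) {
  values <- values[is.finite(values)]
  nb <- length(edges) - 1L
  if (!length(values)) return(intensity_histogram(edges, rep(1 / nb, nb)))
  bins <- findInterval(values, edges, all.inside = TRUE)
  counts <- tabulate(bins, nb)
  intensity_histogram(edges, counts / sum(counts))
}

#' Symmetrized Kullback-Leibler measure between two intensity histograms
#'
#' The J-divergence `sum((p - q) * log(p / q))` after additive smoothing
#' (`eps` added to every bin probability, then renormalization). Symmetric,
#' nonnegative, zero exactly when the histograms coincide, and finite for any
#' smoothed input.
#'
#' @param p,q `intensity_histogram` objects on identical bins.
#' @param eps per-bin additive smoothing applied before renormalization.
#' @return nonnegative scalar.
#' @export
kl_measure <- function(p, q, eps = 1e-6) {
  if (!inherits(p, "intensity_histogram") || !inherits(q, "intensity_histogram"))
    stop("arguments must be intensity_histogram objects")
  if (length(p$bin_edges) != length(q$bin_edges) ||
      max(abs(p$bin_edges - q$bin_edges)) > 1e-9)
    stop("histogram bin mismatch")
  n <- length(p$probabilities)
  ps <- (p$probabilities + eps) / (1 + n * eps)
  qs <- (q$probabilities + eps) / (1 + n * eps)
  sum((ps - qs) * (log(ps) - log(qs)))
}

# shared preparation: foreground threshold, robust range, global bin edges.
# A bright skull shell (CT) is excluded from the histograms: its apparent
# thickness grows with plane obliquity, which would bias the KL objective
# towards tilted planes while carrying no hemispheric-symmetry information.
msp_prep <- function(v, nbins) {
  vals <- as.vector(v$data)
  rng <- stats::quantile(vals, c(0.01, 0.99), names = FALSE)
  if (diff(rng) < 1e-6) stop("no symmetry signal: volume intensity is constant")
  bg <- background_threshold(vals)
  fg <- vals[vals > bg]
  if (length(fg) < 1000) stop("no symmetry signal: too few foreground voxels")
  hi <- Inf
  q995 <- stats::quantile(fg, 0.995, names = FALSE)
  if (q995 * 0.8 > 1.6 * stats::median(fg)) hi <- q995 * 0.7
  fg <- fg[fg < hi]
  fr <- stats::quantile(fg, c(0.005, 0.995), names = FALSE)
  if (diff(fr) < 1e-6) stop("no symmetry signal: foreground intensity is constant")
  list(bg = bg, hi = hi, edges = seq(fr[1], fr[2], length.out = nbins + 1L))
}

# KL objective for an oblique plane: histogram of trilinear samples on the
# plane (foreground only) against a fixed reference distribution. The sample
# positions come in as precomputed in-plane coordinates (uu, vv); a
# low-discrepancy lattice avoids moire between the sample pitch and the
# voxel grid that a regular lattice would produce.
plane_kl_score <- function(v, prep, ref, x0, su, sv, uu, vv, yc, zc, eps) {
  pts <- cbind(x0 + su * (uu - yc) + sv * (vv - zc), uu, vv)
  s <- sample_trilinear(v, pts)
  s <- s[!is.na(s) & s > prep$bg & s < prep$hi]
  if (length(s) < 50) return(-Inf)
  kl_measure(hist_on_edges(s, prep$edges), ref, eps = eps)
}

#' Extract the midsagittal plane by the Kullback-Leibler measure
#'
#' Coarse stage: a volume of interest of sagittal slices is set around the
#' central slice, the first VOI slice serves as the reference distribution,
#' every slice is scored by the KL measure against it, and the maximizer is
#' the coarse MSP (ties resolved towards the volume centre). Fine stage: the
#' plane is parameterized by the sagittal offsets of three corner points of
#' the coarse plane (equivalently, sagittal position plus two tilt slopes); a
#' global tilt/position scan, multi-start coordinate descent and a
#' shrinking-range corner-offset search maximize the KL measure between the
#' resampled oblique plane's distribution and the averaged histogram of the
#' VOI's outer slices (see the methods vignette for why the fine-stage
#' reference differs from the coarse one).
#'
#' @param volume a `vol3d` with at least 16 sagittal slices.
#' @param params optional list: `nbins` (histogram bins, 64), `eps` (KL
#'   smoothing for the coarse slice scores, 1e-6), `fine_eps` (smoothing for
#'   the fine-stage objective, 3e-4), `voi_frac` (VOI half-width as a
#'   fraction of the head's sagittal extent, 0.25), `tilt_max_deg` (tilt
#'   scan half-range, 27), `tilt_step_deg` (base scan step, 3), `n_iter`
#'   (search depth, 4), `grid_n` (plane sampling resolution, 48; the
#'   refinement stages use 2x and 3x).
#' @return a `plane3d`; attribute `diagnostics` carries the coarse slice
#'   index and the final KL score.
#' @export
extract_msp <- function(volume, params = list()) {
  stopifnot_vol(volume)
  p <- modifyList(list(nbins = 64L, eps = 1e-6, fine_eps = 3e-4,
                       voi_frac = 0.25, tilt_max_deg = 27, tilt_step_deg = 3,
                       n_iter = 4L, grid_n = 48L), params)
  d <- dim(volume$data)
  if (d[1] < 16L) stop("need at least 16 sagittal slices")
  prep <- msp_prep(volume, p$nbins)
  ax <- vol_axes(volume)

  # --- coarse stage: best single sagittal slice inside the VOI.
  # The VOI is set from the head's own sagittal extent (not the grid's) so
  # that the reference (first VOI) slice is tissue-dominated: a slice too far
  # lateral carries mostly skull and subarachnoid CSF and no longer
  # discriminates the fissure.
  fgx <- which(apply(volume$data > prep$bg, 1, sum) > 0.002 * d[2] * d[3])
  if (length(fgx) < 16L) stop("no symmetry signal: foreground too thin")
  ic <- round(mean(range(fgx)))
  hx <- diff(range(fgx)) / 2
  hw <- max(6L, round(2 * p$voi_frac * hx))
  voi <- max(1L, ic - hw):min(d[1], ic + hw)
  slice_hist <- function(i) {
    s <- volume$data[i, , ]
    hist_on_edges(s[s > prep$bg & s < prep$hi], prep$edges)
  }
  ref <- slice_hist(voi[1])
  scores <- vapply(voi, function(i) kl_measure(slice_hist(i), ref, eps = p$eps), 0)
  best <- max(scores)
  cand <- voi[scores >= best - 1e-12]
  coarse_i <- cand[which.min(abs(cand - ic))]   # tie-break: nearest centre
  x0 <- ax[[1]][coarse_i]

  # fine-stage reference: the averaged histogram of the VOI's outer slices on
  # both sides. Unlike a single lateral slice it carries every ordinary
  # partial-volume mixture (ventricle walls, subarachnoid rim), so only the
  # genuinely midline features (fissure CSF, falx) remain "novel" and the
  # KL maximum lands on the midsagittal plane rather than on its walls.
  outer <- voi[abs(voi - ic) > hw / 2]
  pr <- rowMeans(vapply(outer, function(i) slice_hist(i)$probabilities,
                        numeric(p$nbins)))
  ref_fine <- intensity_histogram(prep$edges, pr / sum(pr))

  # --- fine stage. The search pivots at the head centroid (the fissure plane
  # passes close to it whatever the head pose), scanning the plane's sagittal
  # position jointly with its two tilts on a shrinking grid.
  fg_counts <- apply(volume$data > prep$bg, c(1, 2), sum)
  xh <- sum(rowSums(fg_counts) * ax[[1]]) / sum(fg_counts)
  fgy <- apply(volume$data > prep$bg, 2, sum)
  fgz <- apply(volume$data > prep$bg, 3, sum)
  yc <- sum(fgy * ax[[2]]) / sum(fgy)
  zc <- sum(fgz * ax[[3]]) / sum(fgz)
  hx_mm <- hx * volume$spacing[1]
  lattice <- function(n) {
    npts <- as.integer(n)^2
    kk <- seq_len(npts)
    phi <- (sqrt(5) - 1) / 2
    depths <- seq(max(1.5, 0.8 * volume$spacing[1]),
                  max(7, 2.5 * volume$spacing[1]), length.out = 8)
    list(u = ax[[2]][1] + (kk - 0.5) / npts * (ax[[2]][d[2]] - ax[[2]][1]),
         v = ax[[3]][1] + ((kk * phi) %% 1) * (ax[[3]][d[3]] - ax[[3]][1]),
         d = depths[(kk %% 8L) + 1L])
  }
  lat1 <- lattice(p$grid_n)
  lat2 <- lattice(round(1.5 * p$grid_n))
  score1 <- function(x, su, sv)
    plane_kl_score(volume, prep, ref_fine, x, su, sv, lat1$u, lat1$v, yc, zc,
                   p$fine_eps)
  score2 <- function(x, su, sv)
    plane_kl_score(volume, prep, ref_fine, x, su, sv, lat2$u, lat2$v, yc, zc,
                   p$fine_eps)

  # global scan: plane tilts (two slopes) x sagittal position
  step <- tan(1.6 * p$tilt_step_deg * pi / 180)
  lim <- tan(p$tilt_max_deg * pi / 180)
  grid1 <- seq(-lim, lim, by = step)
  xs <- unique(c(xh + seq(-6, 6, by = 3), x0))
  cand <- list()
  for (a in grid1) for (b in grid1) {
    if (a^2 + b^2 > lim^2 * 1.05) next
    for (x in xs) {
      sc <- score1(x, a, b)
      cand[[length(cand) + 1L]] <- c(sc, x, a, b)
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 1]), , drop = FALSE]
  # multi-start: dense coordinate descent from the best level-1 candidates
  # that are mutually distinct in tilt (the objective can carry local maxima)
  starts <- cand[1, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    if (nrow(starts) >= 3L) break
    dts <- sqrt((starts[, 3] - cand[i, 3])^2 + (starts[, 4] - cand[i, 4])^2)
    if (all(dts > 2 * step)) starts <- rbind(starts, cand[i, ])
  }
  descend <- function(sx, su, sv, rounds = p$n_iter %/% 2) {
    st <- step
    sc_best <- score2(sx, su, sv)
    for (round in seq_len(rounds)) {
      for (a in su + seq(-st, st, by = st / 8)) {
        sc <- score2(sx, a, sv)
        if (sc > sc_best) { sc_best <- sc; su <- a }
      }
      for (b in sv + seq(-st, st, by = st / 8)) {
        sc <- score2(sx, su, b)
        if (sc > sc_best) { sc_best <- sc; sv <- b }
      }
      for (x in sx + seq(-3, 3, by = 0.5)) {
        sc <- score2(x, su, sv)
        if (sc > sc_best) { sc_best <- sc; sx <- x }
      }
      st <- st / 4
    }
    c(sc_best, sx, su, sv)
  }
  # one descent round from every start, full depth only from the winner
  res <- t(apply(starts, 1, function(s1) descend(s1[2], s1[3], s1[4],
                                                 rounds = 1L)))
  bi <- which.max(res[, 1])
  res2 <- descend(res[bi, 2], res[bi, 3], res[bi, 4])
  sc_best <- res2[1]; sx <- res2[2]; su <- res2[3]; sv <- res2[4]
  # final polish on a denser lattice: the objective's sampling noise shrinks
  # with the sample count, sharpening the last fraction of a degree
  lat3 <- lattice(3 * p$grid_n)
  lat4 <- lattice(4 * p$grid_n)
  score3 <- function(x, su, sv)
    plane_kl_score(volume, prep, ref_fine, x, su, sv, lat3$u, lat3$v, yc, zc,
                   p$fine_eps)
  score4 <- function(x, su, sv)
    plane_kl_score(volume, prep, ref_fine, x, su, sv, lat4$u, lat4$v, yc, zc,
                   p$fine_eps)
  Ey <- ax[[2]][d[2]] - ax[[2]][1]; Ez <- ax[[3]][d[3]] - ax[[3]][1]
  # corners: (ymin,zmin), (ymax,zmin), (ymin,zmax); offsets in mm along x
  o <- c(sx + su * (ax[[2]][1] - yc) + sv * (ax[[3]][1] - zc),
         sx + su * (ax[[2]][d[2]] - yc) + sv * (ax[[3]][1] - zc),
         sx + su * (ax[[2]][1] - yc) + sv * (ax[[3]][d[3]] - zc))
  corners_to_par <- function(o) {
    su <- (o[2] - o[1]) / Ey
    sv <- (o[3] - o[1]) / Ez
    x0 <- o[1] - su * (ax[[2]][1] - yc) - sv * (ax[[3]][1] - zc)
    c(x0, su, sv)
  }
  sc_best <- score3(sx, su, sv)
  r <- volume$spacing[1]
  for (it in seq_len(p$n_iter)) {
    for (ci in 1:3) {
      for (dlt in c(-r, -r / 2, r / 2, r)) {
        o2 <- o; o2[ci] <- o2[ci] + dlt
        pp <- corners_to_par(o2)
        sc <- score3(pp[1], pp[2], pp[3])
        if (sc > sc_best) { sc_best <- sc; o <- o2 }
      }
    }
    r <- r / 2
  }
  pp0 <- corners_to_par(o)
  sx <- pp0[1]; su <- pp0[2]; sv <- pp0[3]
  # last pass: densest lattice, finest steps
  sc_best <- score4(sx, su, sv)
  for (a in su + seq(-0.004, 0.004, by = 0.001)) {
    sc <- score4(sx, a, sv)
    if (sc > sc_best) { sc_best <- sc; su <- a }
  }
  for (b in sv + seq(-0.004, 0.004, by = 0.001)) {
    sc <- score4(sx, su, b)
    if (sc > sc_best) { sc_best <- sc; sv <- b }
  }
  for (x in sx + seq(-0.5, 0.5, by = 0.25)) {
    sc <- score4(x, su, sv)
    if (sc > sc_best) { sc_best <- sc; sx <- x }
  }
  pl <- plane3d(c(1, -su, -sv),
                (sx - su * yc - sv * zc) / sqrt(1 + su^2 + sv^2))
  attr(pl, "diagnostics") <- list(coarse_index = coarse_i, score = sc_best,
                                  background = prep$bg)
  pl
}

#' Extract the midsagittal plane after skull-fit pre-rotation
#'
#' For CT acquisitions with a large head tilt: the skull cross-section on a
#' set of axial slices is fitted with an ellipse; yaw is estimated from the
#' in-plane major-axis orientation and pitch/roll from the slicewise drift of
#' the ellipse centres; the volume is counter-rotated and [extract_msp()] run
#' on the reoriented volume; the pre-rotation is composed back into the
#' returned plane.
#'
#' @param volume a `vol3d` containing a closed high-intensity skull shell.
#' @param params forwarded to [extract_msp()]; additionally `min_ring_px`
#'   (minimum skull pixels per usable slice, 100).
#' @return a `plane3d`; attribute `prerotation` carries the estimated
#'   yaw/pitch/roll (degrees).
#' @export
extract_msp_tilted <- function(volume, params = list()) {
  stopifnot_vol(volume)
  p <- modifyList(list(min_ring_px = 100L), params)
  est <- estimate_head_rotation(volume, p$min_ring_px)
  R <- rotation_matrix(est[1], est[2], est[3])
  ctr <- vol_center(volume)
  lut_air <- min(volume$data)
  vol2 <- if (max(abs(est)) > 0.1)
    rotate_volume(volume, t(R), fill = lut_air, center = ctr) else volume
  pl2 <- extract_msp(vol2, params)
  pl <- if (max(abs(est)) > 0.1) rotate_plane(pl2, R, ctr) else pl2
  attr(pl, "prerotation") <- est
  attr(pl, "diagnostics") <- attr(pl2, "diagnostics")
  pl
}

# estimate (yaw, pitch, roll) in degrees from the skull shell
estimate_head_rotation <- function(volume, min_ring_px = 100L) {
  vals <- as.vector(volume$data)
  bg <- background_threshold(vals)
  fg <- vals[vals > bg]
  skull_thr <- stats::quantile(fg, 0.995, names = FALSE) * 0.8
  skull <- volume$data > skull_thr
  if (mean(skull) < 0.002)
    stop("no skull detected: use the KL method directly (extract_msp)")
  d <- dim(volume$data)
  ax <- vol_axes(volume)
  ks <- which(apply(skull, 3, sum) >= min_ring_px)
  if (length(ks) < 5L)
    stop("no skull detected: use the KL method directly (extract_msp)")
  # shell sanity: the ring must enclose an interior on its central slice
  kmid <- ks[ceiling(length(ks) / 2)]
  ring <- skull[, , kmid]
  interior <- fill_holes_2d(ring) & !ring
  if (sum(interior) < 2 * sum(ring) / 3)
    stop("no skull detected: use the KL method directly (extract_msp)")
  # central band of usable slices
  band <- ks[ks >= stats::quantile(ks, 0.25) & ks <= stats::quantile(ks, 0.75)]
  yaws <- cx <- cy <- zz <- rep(NA_real_, length(band))
  for (i in seq_along(band)) {
    k <- band[i]
    idx <- which(skull[, , k], arr.ind = TRUE)
    ptsk <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]])
    ft <- tryCatch(fit_ellipse(ptsk), error = function(e) NULL)
    if (is.null(ft)) next
    cx[i] <- ft$center[1]; cy[i] <- ft$center[2]; zz[i] <- ax[[3]][k]
    if (ft$a / ft$b > 1.05) {
      # head's major axis is anterior-posterior: yaw = major-axis angle vs +y
      ang <- ft$orientation * 180 / pi - 90
      if (ang > 90) ang <- ang - 180
      if (ang <= -90) ang <- ang + 180
      yaws[i] <- ang
    }
  }
  yaw <- stats::median(yaws, na.rm = TRUE)
  if (!is.finite(yaw)) yaw <- 0
  ok <- is.finite(cx) & is.finite(zz)
  roll <- pitch <- 0
  if (sum(ok) >= 5) {
    roll <- atan(stats::coef(stats::lm(cx[ok] ~ zz[ok]))[2]) * 180 / pi
    pitch <- -atan(stats::coef(stats::lm(cy[ok] ~ zz[ok]))[2]) * 180 / pi
  }
  unname(c(yaw, pitch, roll))
}

fill_holes_2d <- function(m) {
  lab <- label_components(!m)
  border <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                             lab[, ncol(lab)])), 0L)
  m | (lab > 0L & !(lab %in% border))
}
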