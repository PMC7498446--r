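#' Per-ROI intensity statistics
#'
#' Statistics are computed in 3D within each atlas-defined ROI (rather than
#' per acquired slice): voxel count, mean, population SD and the peak height
#' of the normalized 64-bin histogram on the 8-bit intensity scale. Volumes
#' whose intensities exceed \[0, 255\] are linearly rescaled from their robust
#' range first.
#'
#' @param volume `vol3d` scan.
#' @param labels individualized label `vol3d` on the scan grid.
#' @param mask optional binary `vol3d` (e.g. CSF-removed brain) restricting
#'   the statistics; fully removed ROIs are omitted with a warning.
#' @param nbins histogram bins (64).
#' @return data frame: `code`, `n`, `mean`, `sd`, `peak`, plus the histogram
#'   as a matrix attribute `hist` (one row per ROI).
#' @export
roi_stats <- function(volume, labels, mask = NULL, nbins = 64L) {
  stopifnot_vol(volume); stopifnot_vol(labels, "labels")
  if (!same_grid(volume, labels)) stop("labels must live on the scan grid")
  vals <- as.vector(volume$data)
  vals <- rescale_8bit(vals)
  lab <- as.vector(labels$data)
  keep <- lab > 0L
  if (!is.null(mask)) {
    if (!same_grid(volume, mask)) stop("mask grid mismatch")
    removed <- unique(lab[keep & as.vector(mask$data) == 0])
    keep <- keep & as.vector(mask$data) != 0
    gone <- setdiff(removed, unique(lab[keep]))
    if (length(gone))
      warning("ROI(s) fully removed by the mask and omitted: ",
              paste(sort(gone), collapse = ", "))
  }
  if (!any(keep)) stop("all atlas ROIs are empty on this scan")
  lab <- lab[keep]; vals <- vals[keep]
  edges <- seq(0, 256, length.out = nbins + 1L)
  codes <- sort(unique(lab))
  hmat <- matrix(0, length(codes), nbins)
  out <- data.frame(code = codes, n = 0L, mean = 0, sd = 0, peak = 0)
  for (i in seq_along(codes)) {
    x <- vals[lab == codes[i]]
    h <- tabulate(findInterval(x, edges, all.inside = TRUE), nbins)
    h <- h / sum(h)
    hmat[i, ] <- h
    out$n[i] <- length(x)
    out$mean[i] <- mean(x)
    out$sd[i] <- sqrt(mean((x - mean(x))^2))   # population convention
    out$peak[i] <- max(h)
  }
  attr(out, "hist") <- hmat
  attr(out, "bin_edges") <- edges
  out
}

rescale_8bit <- function(vals) {
  r <- range(vals)
  if (r[1] >= 0 && r[2] <= 255) return(vals)
  q <- stats::quantile(vals, c(0.005, 0.995), names = FALSE)
  if (diff(q) <= 0) q <- r
  pmin(255, pmax(0, (vals - q[1]) / diff(q) * 255))
}

#' Atlas-assisted stroke detection by hemispheric asymmetry
#'
#' Every lateralized label pair (anatomy and territory atlases, paired by the
#' legend's mirror codes) is compared between hemispheres; a pair is
#' mismatched when the difference in ROI mean, SD or histogram peak height
#' exceeds its threshold. The affected side and lesion contrast are resolved
#' from the tail of the paired histograms: excess low-intensity mass flags a
#' hypodense lesion (infarct evidence), excess high-intensity mass a
#' hyperdense one (hemorrhage evidence); hyperdense evidence overlapping
#' infarct evidence upgrades the diagnosis to hemorrhagic transformation.
#'
#' @param volume `vol3d` scan (CSF should already be removed via `mask`).
#' @param bundle individualized [atlas_bundle()] on the scan grid.
#' @param mask binary `vol3d`, typically from [remove_csf()].
#' @param thresholds list: `mean` (6), `sd` (6), `peak` (0.05) on the 8-bit
#'   scale; user-settable to move the normality/pathology boundary.
#' @param msp optional [plane3d()]: when given, voxels within
#'   `midline_exclude_mm` of the plane are excluded from the paired
#'   statistics (midline structures -- falx, interhemispheric CSF -- belong
#'   to neither hemisphere and would register as spurious asymmetry under
#'   any small plane-localization error).
#' @param midline_exclude_mm half-width of the excluded midline slab (5).
#' @return object of class `detection_report`: `diagnosis` in
#'   infarct / hemorrhage / infarct_with_hemorrhagic_transformation /
#'   not_detected, a data frame `findings` and the thresholds used.
#' @export
detect_stroke <- function(volume, bundle, mask = NULL,
                          thresholds = list(mean = 6, sd = 6, peak = 0.05),
                          msp = NULL, midline_exclude_mm = 5) {
  stopifnot_vol(volume)
  if (!inherits(bundle, "atlas_bundle")) stop("`bundle` must be an atlas_bundle")
  thr <- modifyList(list(mean = 6, sd = 6, peak = 0.05), thresholds)
  if (!is.null(msp)) {
    keep <- abs(plane_signed_dist(msp, grid_points(volume))) > midline_exclude_mm
    keep <- array(as.integer(keep), dim(volume$data))
    if (!is.null(mask)) keep <- keep * (mask$data != 0)
    mask <- vol_like(volume, keep)
  }
  legend <- bundle$legend
  vals8 <- array(rescale_8bit(as.vector(volume$data)), dim(volume$data))
  v8 <- vol_like(volume, vals8)
  findings <- list()
  ev_masks <- list()
  vt <- bundle$ventricle_template$data != 0
  for (atl in c("anatomy", "territories")) {
    labs <- bundle[[atl]]
    st <- tryCatch(suppressWarnings(roi_stats(v8, labs, mask)),
                   error = function(e) NULL)
    if (is.null(st)) next
    full_n <- tabulate(labs$data[labs$data > 0L], max(labs$data))
    hmat <- attr(st, "hist"); edges <- attr(st, "bin_edges")
    lefts <- legend[legend$laterality == "left" & legend$code %in% st$code, ]
    for (r in seq_len(nrow(lefts))) {
      cl <- lefts$code[r]; cr <- lefts$mirror_code[r]
      il <- match(cl, st$code); ir <- match(cr, st$code)
      if (is.na(il) || is.na(ir)) next
      # a pair whose ROIs were mostly masked away (e.g. ventricles after CSF
      # removal) carries only boundary voxels and is not comparable
      if (st$n[il] < 100L || st$n[ir] < 100L ||
          st$n[il] < 0.3 * full_n[cl] || st$n[ir] < 0.3 * full_n[cr]) next
      # CSF spaces are not parenchyma: skip labels that are mostly ventricle
      if (sum(labs$data == cl & vt) > 0.5 * full_n[cl]) next
      dmean <- st$mean[il] - st$mean[ir]
      dsd <- st$sd[il] - st$sd[ir]
      dpeak <- st$peak[il] - st$peak[ir]
      if (abs(dmean) <= thr$mean && abs(dsd) <= thr$sd &&
          abs(dpeak) <= thr$peak) next
      atts <- attribute_mismatch(hmat[il, ], hmat[ir, ])
      for (att in atts) {
        side <- if (att$left) "left" else "right"
        code <- if (att$left) cl else cr
        ev <- evidence_voxels(v8, bundle[[atl]], mask, code, edges, att$bins)
        slc <- sort(unique(which(apply(ev, 3, any))))
        name <- legend$name[legend$code == code]
        overl <- overlapped_names(ev, bundle, legend, atl)
        findings[[length(findings) + 1L]] <- data.frame(
          atlas = atl, label = name, code = code, side = side,
          kind = att$kind,
          mean_left = st$mean[il], mean_right = st$mean[ir],
          delta_mean = dmean, delta_sd = dsd, delta_peak = dpeak,
          slices = paste(slc, collapse = ","),
          overlaps = overl, stringsAsFactors = FALSE)
        ev_masks[[length(ev_masks) + 1L]] <- list(kind = att$kind, mask = ev)
      }
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(atlas = character(), label = character(), code = integer(),
               side = character(), kind = character(), mean_left = numeric(),
               mean_right = numeric(), delta_mean = numeric(),
               delta_sd = numeric(), delta_peak = numeric(),
               slices = character(), overlaps = character())
  has_hypo <- any(findings$kind == "hypodense")
  has_hyper <- any(findings$kind == "hyperdense")
  diagnosis <- if (!nrow(findings)) "not_detected"
    else if (has_hypo && has_hyper && evidence_overlap(ev_masks))
      "infarct_with_hemorrhagic_transformation"
    else if (has_hypo) "infarct"
    else "hemorrhage"
  structure(list(diagnosis = diagnosis, findings = findings,
                 thresholds = thr), class = "detection_report")
}

# which side and contrast explain a mismatched pair: compare tail mass of the
# left and right ROI histograms outside the shared mode region. A secondary
# attribution (e.g. a hyperdense core inside a hypodense lesion) is also
# reported when its tail excess is comparable to the dominant one.
attribute_mismatch <- function(hl, hr, guard = 2L, guard2 = 6L,
                               secondary_frac = 0.35) {
  # the reference mode is where BOTH sides carry mass (normal tissue); a
  # dominant unilateral lesion must not be mistaken for the tissue peak
  mode_bin <- which.max(pmin(hl, hr))
  nb <- length(hl)
  tails <- function(g) list(
    low = seq_len(max(mode_bin - g - 1L, 0L)),
    high = if (mode_bin + g + 1L <= nb) (mode_bin + g + 1L):nb else integer())
  t1 <- tails(guard)
  d_low <- sum(hl[t1$low] - hr[t1$low])
  d_high <- sum(hl[t1$high] - hr[t1$high])
  cand <- c(left_hypo = d_low, right_hypo = -d_low,
            left_hyper = d_high, right_hyper = -d_high)
  mk <- function(k, tl) {
    left <- startsWith(k, "left")
    kind <- if (endsWith(k, "hypo")) "hypodense" else "hyperdense"
    sel <- if (kind == "hypodense") tl$low else tl$high
    dif <- hl[sel] - hr[sel]
    # only bins with a clear one-sided excess count as lesion evidence
    bins <- sel[if (left) dif > 1e-3 else dif < -1e-3]
    list(left = left, kind = kind, bins = bins)
  }
  dom <- names(which.max(cand))
  out <- list(mk(dom, t1))
  # a secondary attribution (the opposite contrast) must be a genuine second
  # mode well away from the tissue peak: a mass deficit right beside the mode
  # on one side is just the dominant lesion's displaced tissue
  t2 <- tails(guard2)
  d_low2 <- sum(hl[t2$low] - hr[t2$low])
  d_high2 <- sum(hl[t2$high] - hr[t2$high])
  sec <- if (endsWith(dom, "hypo"))
    c(left_hyper = d_high2, right_hyper = -d_high2)
  else c(left_hypo = d_low2, right_hypo = -d_low2)
  if (max(sec) > secondary_frac * cand[dom])
    out[[2]] <- mk(names(which.max(sec)), t2)
  out
}

evidence_voxels <- function(v8, labels, mask, code, edges, bins) {
  m <- labels$data == code
  if (!is.null(mask)) m <- m & mask$data != 0
  if (!length(bins)) return(m & FALSE)
  b <- array(findInterval(v8$data, edges, all.inside = TRUE), dim(v8$data))
  m & array(b %in% bins, dim(v8$data))
}

overlapped_names <- function(ev, bundle, legend, atl) {
  other <- if (atl == "anatomy") "territories" else "anatomy"
  codes <- setdiff(unique(bundle[[other]]$data[ev]), 0L)
  paste(sort(legend$name[legend$code %in% codes]), collapse = "; ")
}

evidence_overlap <- function(ev_masks) {
  hypo <- Reduce(`|`, lapply(Filter(function(e) e$kind == "hypodense", ev_masks),
                             `[[`, "mask"))
  hyper <- Reduce(`|`, lapply(Filter(function(e) e$kind == "hyperdense", ev_masks),
                              `[[`, "mask"))
  if (is.null(hypo) || is.null(hyper)) return(FALSE)
  # dilate the hypodense evidence a little: transformation sits inside or at
  # the rim of the infarct
  any(hyper & dilate_mask(hypo, 3))
}

#' @export
print.detection_report <- function(x, ...) {
  cat(format_detection_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text detection report
#' @param x a `detection_report`.
#' @return character vector of report lines.
#' @export
format_detection_report <- function(x) {
  out <- c(sprintf("DIAGNOSIS: %s", x$diagnosis),
           sprintf("thresholds: mean %g, sd %g, peak %g",
                   x$thresholds$mean, x$thresholds$sd, x$thresholds$peak))
  for (atl in c("territories", "anatomy")) {
    f <- x$findings[x$findings$atlas == atl, ]
    if (!nrow(f)) next
    out <- c(out, sprintf("-- %s --", atl))
    for (i in seq_len(nrow(f)))
      out <- c(out, sprintf(
        "%s (%s, %s): mean L %.1f / R %.1f; slices %s; overlaps: %s",
        f$label[i], f$side[i], f$kind[i], f$mean_left[i], f$mean_right[i],
        f$slices[i], f$overlaps[i]))
  }
  if (!nrow(x$findings)) out <- c(out, "no mismatched ROI pairs")
  out
}

#' Quantify an ROI by atlas overlap
#'
#' Lists every atlas structure overlapping the ROI with its contribution in
#' cm^3 and percent of ROI volume.
#'
#' @param roi_mask binary `vol3d`.
#' @param labels co-registered label `vol3d`.
#' @param legend atlas legend (code/name data frame).
#' @return object of class `roi_quantification`: data frame `structures`
#'   (name, code, volume_cm3, percent) and `totals`.
#' @export
quantify_roi <- function(roi_mask, labels, legend = NULL) {
  stopifnot_vol(roi_mask); stopifnot_vol(labels, "labels")
  if (!same_grid(roi_mask, labels)) stop("grid mismatch")
  sel <- roi_mask$data != 0
  if (!any(sel)) stop("empty ROI")
  vml <- prod(roi_mask$spacing) / 1000   # cm^3 per voxel
  codes <- as.vector(labels$data[sel])
  tab <- table(codes)
  code_v <- as.integer(names(tab))
  vol_v <- as.numeric(tab) * vml
  pct <- as.numeric(tab) / sum(tab) * 100
  nm <- if (!is.null(legend)) {
    n <- legend$name[match(code_v, legend$code)]
    n[is.na(n)] <- ifelse(code_v[is.na(n)] == 0L, "unlabeled", "unknown")
    n
  } else ifelse(code_v == 0L, "unlabeled", paste("label", code_v))
  ord <- order(-vol_v)
  structure(list(
    structures = data.frame(name = nm, code = code_v, volume_cm3 = vol_v,
                            percent = pct)[ord, ],
    totals = list(roi_volume_cm3 = sum(tab) * vml, n_structures = length(tab))),
    class = "roi_quantification")
}

#' @export
print.roi_quantification <- function(x, ...) {
  cat(sprintf("<roi_quantification> ROI %.2f cm^3 across %d structure(s)\n",
              x$totals$roi_volume_cm3, x$totals$n_structures))
  print(x$structures, row.names = FALSE)
  invisible(x)
}

#' Thrombolysis decision ratios
#'
#' All volumes and ratios are computed in 3D: the infarct-to-territory ratio
#' for the MCA (with terminal/penetrating sub-ratios), ACA and PCA territories
#' on the infarct's majority side, and the diffusion-perfusion mismatch ratio
#' (penumbra / infarct). The hemorrhagic-transformation risk flags use strict
#' inequalities against the one-third and one-half thresholds.
#'
#' @param infarct_mask binary `vol3d`.
#' @param territories individualized territory label `vol3d`.
#' @param legend atlas legend.
#' @param penumbra_mask optional binary `vol3d`.
#' @return object of class `thrombolysis_assessment`.
#' @export
assess_thrombolysis <- function(infarct_mask, territories, legend,
                                penumbra_mask = NULL) {
  stopifnot_vol(infarct_mask); stopifnot_vol(territories, "territories")
  if (!same_grid(infarct_mask, territories)) stop("grid mismatch")
  vml <- voxel_ml(infarct_mask)
  inf <- infarct_mask$data != 0
  inf_ml <- sum(inf) * vml
  pen_ml <- NULL
  if (!is.null(penumbra_mask)) {
    if (!same_grid(infarct_mask, penumbra_mask)) stop("grid mismatch")
    pen_ml <- sum(penumbra_mask$data != 0) * vml
  }
  if (inf_ml == 0) {
    warning("empty infarct mask: territory ratios reported as 0")
    side <- NA_character_
  } else {
    codes <- territories$data[inf]
    lat <- legend$laterality[match(codes, legend$code)]
    side <- if (sum(lat == "left", na.rm = TRUE) >=
                sum(lat == "right", na.rm = TRUE)) "left" else "right"
  }
  terr_ratio <- function(parcels) {
    if (is.na(side)) return(0)
    pat <- paste0("^", side, " (", paste(parcels, collapse = "|"), ")$")
    codes <- legend$code[grepl(pat, legend$name)]
    tmask <- territories$data %in% codes
    tv <- sum(tmask)
    if (tv == 0) return(0)
    sum(inf & tmask) / tv
  }
  mca <- terr_ratio(c("MCA terminal", "MCA penetrating"))
  out <- list(
    infarct_volume_ml = inf_ml,
    penumbra_volume_ml = pen_ml,
    mismatch_ratio = if (is.null(pen_ml) || inf_ml == 0) NULL
                     else pen_ml / inf_ml,
    infarct_to_MCA_ratio = mca,
    infarct_to_ACA_ratio = terr_ratio("ACA"),
    infarct_to_PCA_ratio = terr_ratio("PCA"),
    MCA_terminal_ratio = terr_ratio("MCA terminal"),
    MCA_penetrating_ratio = terr_ratio("MCA penetrating"),
    side = side,
    exceeds_one_third = mca > 1 / 3,
    exceeds_one_half = mca > 1 / 2)
  structure(out, class = "thrombolysis_assessment")
}

#' @export
print.thrombolysis_assessment <- function(x, ...) {
  cat(sprintf("<thrombolysis_assessment> infarct %.1f ml (%s side)\n",
              x$infarct_volume_ml, x$side))
  if (!is.null(x$mismatch_ratio))
    cat(sprintf("  mismatch ratio (penumbra/infarct): %.2f\n", x$mismatch_ratio))
  cat(sprintf("  infarct/MCA %.3f (terminal %.3f, penetrating %.3f), ACA %.3f, PCA %.3f\n",
              x$infarct_to_MCA_ratio, x$MCA_terminal_ratio,
              x$MCA_penetrating_ratio, x$infarct_to_ACA_ratio,
              x$infarct_to_PCA_ratio))
  cat(sprintf("  exceeds 1/3: %s; exceeds 1/2: %s\n",
              x$exceeds_one_third, x$exceeds_one_half))
  invisible(x)
}
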