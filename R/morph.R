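# Binary-mask utilities: connected components (8-conn in 2D, 26-conn in 3D),
# ball dilation/erosion, hole filling, histogram thresholds. 2D labeling is
# delegated to EBImage::bwlabel (4-connected); diagonal and inter-slice
# equivalences are merged through an igraph components pass.

arr_shift <- function(a, d, fill = 0L) {
  # shift array contents by integer offsets d (values move towards +d)
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", length(dm))
  for (ax in seq_along(dm)) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- seq_len(dm[ax] - d[ax]) + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
    }
    if (dm[ax] <= abs(d[ax])) return(out)
  }
  if (length(dm) == 2L) out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

label_components_2d <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  # merge diagonal neighbours for 8-connectivity
  pairs <- NULL
  for (d in list(c(1, 1), c(1, -1))) {
    sh <- arr_shift(lab, d)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], sh[sel]))
  }
  relabel_merge(lab, pairs)
}

label_components_3d <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  offs <- 0L
  for (k in seq_len(dm[3])) {
    lk <- EBImage::bwlabel(matrix(as.numeric(mask[, , k]), dm[1]))
    lk <- matrix(as.integer(lk), dm[1])
    pos <- lk > 0L
    if (any(pos)) {
      lk[pos] <- lk[pos] + offs
      offs <- max(lk)
      lab[, , k] <- lk
    }
  }
  if (offs == 0L) return(lab)
  pairs <- NULL
  # in-plane diagonals (8-connectivity) and all 9 inter-slice shifts (26-conn)
  shifts <- list(c(1, 1, 0), c(1, -1, 0))
  for (dx in -1:1) for (dy in -1:1) shifts <- c(shifts, list(c(dx, dy, 1)))
  for (d in shifts) {
    sh <- arr_shift(lab, d)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], sh[sel]))
  }
  relabel_merge(lab, pairs)
}

relabel_merge <- function(lab, pairs) {
  n <- max(lab)
  if (n == 0L) return(lab)
  if (is.null(pairs)) map <- seq_len(n)
  else {
    # de-duplicate via scalar keys (unique() on a 2-column matrix is slow)
    lo <- pmin(pairs[, 1], pairs[, 2]); hi <- pmax(pairs[, 1], pairs[, 2])
    key <- unique(lo * (n + 1) + hi)
    pairs <- cbind(key %/% (n + 1), key %% (n + 1))
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    map <- as.integer(igraph::components(g)$membership)
  }
  # compact label ids
  used <- sort(unique(map[unique(lab[lab > 0L])]))
  compact <- integer(max(map))
  compact[used] <- seq_along(used)
  out <- lab
  out[lab > 0L] <- compact[map[lab[lab > 0L]]]
  out
}

#' Label connected components of a binary mask
#'
#' 8-connectivity for matrices, 26-connectivity for 3D arrays.
#' @param mask logical/0-1 matrix or 3D array.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  if (is.matrix(mask)) label_components_2d(mask)
  else if (length(dim(mask)) == 3L) label_components_3d(mask)
  else stop("`mask` must be 2D or 3D")
}

ball_offsets <- function(r_mm, spacing) {
  rr <- pmax(0L, floor(r_mm / spacing + 1e-9))
  g <- expand.grid(dx = -rr[1]:rr[1], dy = -rr[2]:rr[2], dz = -rr[3]:rr[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
          (g$dz * spacing[3])^2 <= r_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Dilate / erode a 3D binary mask with a metric ball
#'
#' @param mask logical 3D array.
#' @param r_mm ball radius in mm.
#' @param spacing voxel spacing, numeric(3) mm.
#' @return logical array.
#' @export
dilate_mask <- function(mask, r_mm, spacing = c(1, 1, 1)) {
  offs <- ball_offsets(r_mm, spacing)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out | arr_shift(mask, offs[i, ], FALSE)
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, r_mm, spacing = c(1, 1, 1)) {
  offs <- ball_offsets(r_mm, spacing)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out & arr_shift(mask, offs[i, ], TRUE)
  out & TRUE
}

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, r_mm, spacing = c(1, 1, 1))
  dilate_mask(erode_mask(mask, r_mm, spacing), r_mm, spacing)

#' Fill interior cavities of a 3D binary mask
#'
#' Background components not connected to the array border become foreground.
#' @param mask logical 3D array.
#' @return logical array.
#' @export
fill_holes <- function(mask) {
  comp <- label_components(!mask)
  dm <- dim(mask)
  border <- unique(c(comp[c(1, dm[1]), , ], comp[, c(1, dm[2]), ],
                     comp[, , c(1, dm[3])]))
  border <- setdiff(border, 0L)
  cavity <- array(comp > 0L & !(comp %in% border), dm)
  mask | cavity
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance over a binned histogram; returns the
#' threshold value (right bin edge of the lower class).
#' @param x numeric vector.
#' @param nbins histogram bins.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(nbins, pmax(1L, 1L + floor((x - r[1]) / diff(r) * nbins))),
                nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  bc <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  # the criterion is flat across empty gaps: take the plateau midpoint
  mids[round(mean(which(bc >= max(bc) - 1e-12)))]
}

# intensity separating the background (air) peak from the foreground: the
# first valley after the histogram mode (smoothed), falling back to the
# point where the peak has decayed to a small fraction of its height
background_threshold <- function(x, nbins = 256, frac = 0.01) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  bw <- diff(r) / nbins
  h <- tabulate(pmin(nbins, pmax(1L, 1L + floor((x - r[1]) / bw))), nbins)
  hs <- as.numeric(stats::filter(h, rep(1 / 9, 9), sides = 2))
  hs[is.na(hs)] <- h[is.na(hs)]
  pk <- which.max(hs)
  i <- pk
  while (i < nbins - 1L &&
         !(hs[i] < 0.5 * hs[pk] && hs[i + 1L] >= hs[i]) &&
         hs[i] > frac * hs[pk]) i <- i + 1L
  r[1] + i * bw
}

# separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
# The kernel is normalized; array edges shade towards zero, which is
# irrelevant for head volumes surrounded by air.
gauss_smooth_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[min(ax, length(sigma_vox))]
    if (s <= 0) next
    r <- max(1L, ceiling(2.5 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, d)
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L); off[ax] <- j - r - 1L
      acc <- acc + k[j] * arr_shift(a, off, 0)
    }
    a <- acc
  }
  a
}
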