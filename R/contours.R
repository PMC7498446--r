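#' Per-slice lesion contour sets
#'
#' A contour set is the file-exchange form of a binary region: for each axial
#' slice, a list of closed simple polygons with vertices in world mm
#' coordinates `(x, y)`. Outer boundaries wind counter-clockwise in slice
#' coordinates; cavities (holes) wind clockwise and are resolved by the
#' even-odd fill rule. Polygons are stored with the first vertex repeated as
#' the last (explicit closure).
#'
#' @param slices list of `list(slice_index =, polygons = list(matrix))`.
#' @param grid list with `shape` (integer(3)), `spacing` and `origin`
#'   (numeric(3), mm) describing the reference voxel grid.
#' @return object of class `contour_set`.
#' @export
contour_set <- function(slices, grid) {
  stopifnot(is.list(slices), is.list(grid))
  grid$shape <- as.integer(grid$shape)
  if (length(grid$shape) != 3L) stop("grid shape must have 3 axes")
  for (s in slices) {
    if (s$slice_index < 1L || s$slice_index > grid$shape[3])
      stop("slice index outside grid")
    for (p in s$polygons) {
      p <- rbind(p)
      if (nrow(p) < 4L || any(p[1, ] != p[nrow(p), ]))
        stop("open polygon: first and last vertex must coincide")
    }
  }
  structure(list(slices = slices, grid = grid), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  np <- sum(vapply(x$slices, function(s) length(s$polygons), 1L))
  cat(sprintf("<contour_set> %d polygon(s) on %d slice(s), grid %s\n",
              np, length(x$slices), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  sum(p[-n, 1] * p[-1, 2] - p[-1, 1] * p[-n, 2]) / 2
}

#' Trace closed contours around a binary mask
#'
#' Boundaries follow voxel edges (vertices at voxel corners), so that
#' rasterizing the result with [mask_from_contours()] reproduces the mask
#' voxel-for-voxel. Outer boundaries are returned counter-clockwise.
#'
#' @param mask a `vol3d` whose data is logical or 0/1.
#' @return a `contour_set` on the mask's grid.
#' @export
contours_from_mask <- function(mask) {
  stopifnot_vol(mask, "mask")
  m <- mask$data != 0
  d <- dim(m)
  sx <- mask$spacing[1]; sy <- mask$spacing[2]
  ox <- mask$origin[1]; oy <- mask$origin[2]
  slices <- list()
  for (k in seq_len(d[3])) {
    mk <- m[, , k]
    if (!any(mk)) next
    polys <- trace_slice_boundaries(mk)
    # corner indices -> world mm (corner c corresponds to ox + (c - 1.5) * sx)
    polys <- lapply(polys, function(p)
      cbind(ox + (p[, 1] - 1.5) * sx, oy + (p[, 2] - 1.5) * sy))
    slices[[length(slices) + 1L]] <-
      list(slice_index = k, polygons = polys)
  }
  contour_set(slices, list(shape = d, spacing = mask$spacing,
                           origin = mask$origin))
}

# boundary tracing on a logical matrix; vertices are corner indices where
# corner (a, b) sits at the lower-left of pixel (a, b). Directed edges keep
# the interior on the left, giving CCW outer loops and CW holes.
trace_slice_boundaries <- function(mk) {
  idx <- which(mk, arr.ind = TRUE)
  pad <- function(di, dj) {
    nb <- idx; nb[, 1] <- nb[, 1] + di; nb[, 2] <- nb[, 2] + dj
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(mk) & nb[, 2] >= 1 & nb[, 2] <= ncol(mk)
    out <- rep(FALSE, nrow(idx))
    out[ok] <- mk[nb[ok, , drop = FALSE]]
    out
  }
  edges <- NULL  # columns: x1 y1 x2 y2 (corner indices)
  i <- idx[, 1]; j <- idx[, 2]
  b <- !pad(0, -1)  # bottom open -> edge +x
  if (any(b)) edges <- rbind(edges, cbind(i[b], j[b], i[b] + 1L, j[b]))
  r <- !pad(1, 0)   # right open -> edge +y
  if (any(r)) edges <- rbind(edges, cbind(i[r] + 1L, j[r], i[r] + 1L, j[r] + 1L))
  t <- !pad(0, 1)   # top open -> edge -x
  if (any(t)) edges <- rbind(edges, cbind(i[t] + 1L, j[t] + 1L, i[t], j[t] + 1L))
  l <- !pad(-1, 0)  # left open -> edge -y
  if (any(l)) edges <- rbind(edges, cbind(i[l], j[l] + 1L, i[l], j[l]))
  nc <- max(edges[, c(1, 3)]) + 1L
  key <- function(x, y) x + (y - 1L) * nc
  starts <- key(edges[, 1], edges[, 2])
  remaining <- rep(TRUE, nrow(edges))
  by_start <- split(seq_len(nrow(edges)), starts)
  polys <- list()
  while (any(remaining)) {
    e0 <- which(remaining)[1]
    loop <- edges[e0, 1:2, drop = TRUE]
    cur <- e0
    pts <- list(loop)
    repeat {
      remaining[cur] <- FALSE
      nxt_corner <- edges[cur, 3:4]
      pts[[length(pts) + 1L]] <- nxt_corner
      if (all(nxt_corner == loop)) break
      cand <- by_start[[as.character(key(nxt_corner[1], nxt_corner[2]))]]
      cand <- cand[remaining[cand]]
      if (length(cand) == 0L) stop("boundary tracing failed (open chain)")
      if (length(cand) == 1L) cur <- cand
      else {
        # ambiguous corner (diagonal touch): take the sharpest left turn
        dirv <- edges[cur, 3:4] - edges[cur, 1:2]
        turns <- vapply(cand, function(e) {
          dv <- edges[e, 3:4] - edges[e, 1:2]
          atan2(dirv[1] * dv[2] - dirv[2] * dv[1],
                dirv[1] * dv[1] + dirv[2] * dv[2])
        }, 0)
        cur <- cand[which.max(turns)]
      }
    }
    polys[[length(polys) + 1L]] <- do.call(rbind, pts)
  }
  polys
}

#' Rasterize a contour set to a binary mask (even-odd rule)
#'
#' @param cs a `contour_set`.
#' @param grid optional `vol3d` supplying the target grid (defaults to the
#'   contour set's own grid).
#' @return a `vol3d` with 0/1 data.
#' @export
mask_from_contours <- function(cs, grid = NULL) {
  if (!inherits(cs, "contour_set")) stop("`cs` must be a contour_set")
  if (is.null(grid)) {
    g <- cs$grid
    grid <- vol3d(array(0L, g$shape), g$spacing, g$origin)
  }
  stopifnot_vol(grid, "grid")
  d <- dim(grid$data)
  ax <- vol_axes(grid)
  out <- array(FALSE, d)
  for (s in cs$slices) {
    k <- s$slice_index
    if (k < 1L || k > d[3]) next
    cross <- matrix(0L, d[1], d[2])
    for (p in s$polygons) {
      p <- rbind(p)
      if (nrow(p) < 4L || any(p[1, ] != p[nrow(p), ]))
        stop("open polygon: first and last vertex must coincide")
      for (e in seq_len(nrow(p) - 1L)) {
        y1 <- p[e, 2]; y2 <- p[e + 1L, 2]
        if (y1 == y2) next
        ylo <- min(y1, y2); yhi <- max(y1, y2)
        rows <- which(ax[[2]] >= ylo & ax[[2]] < yhi)  # half-open in y
        if (!length(rows)) next
        xint <- p[e, 1] + (ax[[2]][rows] - y1) * (p[e + 1L, 1] - p[e, 1]) / (y2 - y1)
        for (ri in seq_along(rows)) {
          hit <- ax[[1]] < xint[ri]
          cross[hit, rows[ri]] <- cross[hit, rows[ri]] + 1L
        }
      }
    }
    out[, , k] <- out[, , k] | (cross %% 2L == 1L)
  }
  vol_like(grid, array(as.integer(out), d))
}

#' Read / write the JSON contour file format (version 1)
#'
#' Layout: `{"version": "1.0", "grid": {"shape", "spacing_mm", "origin_mm"},
#' "slices": [{"slice_index": k, "polygons": [[[x_mm, y_mm], ...], ...]}]}`.
#' Readers reject unknown major versions.
#'
#' @param cs a `contour_set`.
#' @param path file path.
#' @export
write_contours <- function(cs, path) {
  doc <- list(
    version = jsonlite::unbox("1.0"),
    grid = list(shape = cs$grid$shape,
                spacing_mm = cs$grid$spacing,
                origin_mm = cs$grid$origin),
    slices = lapply(cs$slices, function(s) list(
      slice_index = jsonlite::unbox(s$slice_index),
      polygons = lapply(s$polygons, function(p) unname(apply(p, 1, as.numeric,
                                                             simplify = FALSE)))))
  )
  jsonlite::write_json(doc, path, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- as.character(j$version)
  if (!startsWith(ver, "1.")) stop("unsupported contour file major version: ", ver)
  grid <- list(shape = as.integer(unlist(j$grid$shape)),
               spacing = as.numeric(unlist(j$grid$spacing_mm)),
               origin = as.numeric(unlist(j$grid$origin_mm)))
  slices <- lapply(j$slices, function(s) list(
    slice_index = as.integer(s$slice_index),
    polygons = lapply(s$polygons, function(p)
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))))))
  contour_set(slices, grid)
}
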