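#' Plane in world coordinates
#'
#' Planes are stored as a unit normal and a signed offset: the plane is
#' `{x : <normal, x> = offset}` with distances in mm. The sign is canonical:
#' the first nonzero component of the normal is positive.
#'
#' @param normal numeric(3), need not be unit length.
#' @param offset signed distance (mm) from the world origin along the normal.
#' @return object of class `plane3d`.
#' @export
plane3d <- function(normal, offset) {
  normal <- as.numeric(normal)
  n2 <- sqrt(sum(normal^2))
  if (!is.finite(n2) || n2 < 1e-12) stop("degenerate plane normal")
  normal <- normal / n2
  offset <- as.numeric(offset)
  # canonical sign: first nonzero component positive
  nz <- which(abs(normal) > 1e-12)[1]
  if (normal[nz] < 0) { normal <- -normal; offset <- -offset }
  structure(list(normal = normal, offset = offset), class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d> normal (%s), offset %.3f mm\n",
              paste(sprintf("%.4f", x$normal), collapse = ", "), x$offset))
  invisible(x)
}

#' Plane through three points
#' @param p1,p2,p3 numeric(3) world points (mm), not collinear.
#' @return a `plane3d`.
#' @export
plane_from_points <- function(p1, p2, p3) {
  n <- crossprod3(p2 - p1, p3 - p1)
  plane3d(n, sum((n / sqrt(sum(n^2))) * p1))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two planes (degrees)
#'
#' The acute angle between the plane normals; orientation-insensitive.
#' @param a,b `plane3d` objects.
#' @export
plane_angle <- function(a, b) {
  d <- abs(sum(a$normal * b$normal))
  acos(min(1, d)) * 180 / pi
}

# signed distances of points (n x 3) from plane
plane_signed_dist <- function(plane, pts) {
  as.vector(rbind(pts) %*% plane$normal) - plane$offset
}

#' Rotate a plane about a centre point
#' @param plane a `plane3d`.
#' @param R 3 x 3 rotation matrix.
#' @param center rotation centre (mm).
#' @return rotated `plane3d`.
#' @export
rotate_plane <- function(plane, R, center) {
  n <- as.vector(R %*% plane$normal)
  # a point on the plane, rotated
  p <- plane$offset * plane$normal
  p2 <- as.vector(R %*% (p - center)) + center
  plane3d(n, sum(n / sqrt(sum(n^2)) * p2))
}

#' Serialize / deserialize a plane as JSON
#' @param plane a `plane3d`.
#' @param path file path.
#' @export
write_plane <- function(plane, path) {
  jsonlite::write_json(list(normal = plane$normal, offset = plane$offset),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plane3d(j$normal, j$offset)
}
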