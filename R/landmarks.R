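#' Talairach-style landmark set
#'
#' The AC and PC are full 3D points (mm, RAS world coordinates); the six
#' cortical landmarks are single coordinates along their own axis (L/R on x,
#' A/P on y, S/I on z), following the modified-landmark convention in which
#' one coordinate per cortical landmark suffices. The optional extended
#' landmarks (top of the corpus callosum and most ventral orbito-frontal
#' point, both z coordinates) double the vertical subdivision.
#'
#' @param AC,PC numeric(3) commissure points (mm).
#' @param L,R,A,P,S,I cortical extreme coordinates (mm) on their axes.
#' @param CC_top,OF_ventral optional extended z coordinates (mm).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(AC, PC, L, R, A, P, S, I,
                         CC_top = NULL, OF_ventral = NULL) {
  AC <- as.numeric(AC); PC <- as.numeric(PC)
  if (length(AC) != 3L || length(PC) != 3L) stop("AC and PC must be 3-points")
  if (!(A > AC[2] && AC[2] > PC[2] && PC[2] > P))
    stop("landmark ordering violated: need A > AC_y > PC_y > P")
  if (!(L < R)) stop("landmark ordering violated: need L < R")
  if (!(I < S)) stop("landmark ordering violated: need I < S")
  if (!is.null(CC_top) || !is.null(OF_ventral)) {
    if (is.null(CC_top) || is.null(OF_ventral))
      stop("extended landmarks require both CC_top and OF_ventral")
    if (!(I < OF_ventral && OF_ventral < AC[3] && AC[3] < CC_top && CC_top < S))
      stop("landmark ordering violated: need I < OF_ventral < AC_z < CC_top < S")
  }
  structure(list(AC = AC, PC = PC, L = L, R = R, A = A, P = P, S = S, I = I,
                 CC_top = CC_top, OF_ventral = OF_ventral),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> AC (%s), PC (%s)\n",
              paste(sprintf("%.1f", x$AC), collapse = ", "),
              paste(sprintf("%.1f", x$PC), collapse = ", ")))
  cat(sprintf("  L %.1f R %.1f | P %.1f A %.1f | I %.1f S %.1f%s\n",
              x$L, x$R, x$P, x$A, x$I, x$S,
              if (!is.null(x$CC_top))
                sprintf(" | OF %.1f CC %.1f", x$OF_ventral, x$CC_top) else ""))
  invisible(x)
}

has_extended <- function(lm) !is.null(lm$CC_top) && !is.null(lm$OF_ventral)

# --- normalized (atlas) space -----------------------------------------------
# A Talairach-like bounding box with the AC at the world origin and axes
# right/anterior/superior. Cortical extents follow the classical proportional
# box (L/R +-68, A +70, P -102, S +74, I -44 mm); the AC-PC distance is 24 mm.
# The brain ellipsoid inscribed in that box has centre (0, -16, 15) and
# semi-axes (68, 86, 59). Voxel centres avoid x = 0 so every lateralized
# label has an exact mirror voxel.

ATLAS_SPACING <- c(2, 2, 2)
ATLAS_SHAPE <- c(90L, 108L, 90L)
ATLAS_ORIGIN <- c(-89, -125, -71)

atlas_space <- function() {
  list(shape = ATLAS_SHAPE, spacing = ATLAS_SPACING, origin = ATLAS_ORIGIN,
       landmarks = atlas_landmarks(),
       brain_center = c(0, -16, 15), brain_semi = c(68, 86, 59))
}

#' Landmarks of the normalized atlas space
#' @return a [landmark_set()] with extended landmarks.
#' @export
atlas_landmarks <- function() {
  landmark_set(AC = c(0, 0, 0), PC = c(0, -24, 0),
               L = -68, R = 68, A = 70, P = -102, S = 74, I = -44,
               CC_top = 36, OF_ventral = -16)
}

# Fractional placement of landmarks on the midsagittal cortex ellipse,
# calibrated so that on the atlas-space ellipse (centre (-16, 15), a = 86,
# b = 59 in (y, z)) the construction reproduces the stored atlas landmarks.
ellipse_landmark_fractions <- function() {
  list(ac_major = 16 / 86, ac_minor = -15 / 59,
       pc_major = -8 / 86, pc_minor = -15 / 59,
       cc_minor = 21 / 59, of_minor = -31 / 59)
}
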