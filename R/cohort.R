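#' Case record: one patient's scan, lesion contours and clinical variables
#'
#' @param id case identifier.
#' @param lesion_contours a non-empty [contour_set()].
#' @param variables named numeric vector/list of clinical variables.
#' @param scan optional `vol3d` (synthetic cohorts may carry contours only).
#' @param to_psa normalization into PSA space: either `"identity"` (the case
#'   already lives in the normalized space) or a `pwl_transform` mapping the
#'   atlas space to the case's scan space; `NULL` defers to the mapping
#'   pipeline at [normalize_case()] time.
#' @return object of class `case_record`.
#' @export
case_record <- function(id, lesion_contours, variables, scan = NULL,
                        to_psa = "identity") {
  if (!inherits(lesion_contours, "contour_set")) stop("contour_set required")
  if (!length(lesion_contours$slices)) stop("empty contours")
  variables <- as.list(variables)
  if (!length(names(variables)) || any(names(variables) == ""))
    stop("variables must be named")
  structure(list(id = id, scan = scan, lesion_contours = lesion_contours,
                 variables = variables, to_psa = to_psa),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s: %d contour slice(s), %d variable(s)\n",
              x$id, length(x$lesion_contours$slices), length(x$variables)))
  invisible(x)
}

#' Cohort specification
#'
#' Couples lesion geometry to outcome variables: each entry of `coupling` is
#' `list(fn = function(centroid_mm, volume_ml) value, noise_sd = sd)`. Lesions
#' are spheres placed uniformly inside the normalized-space brain (kept fully
#' interior), with volumes drawn uniformly from `lesion_volume_range_ml`.
#'
#' @param n_cases number of cases (>= 1).
#' @param outcome_names character vector (non-empty), e.g. mRS_day90.
#' @param coupling named list of couplings per outcome; outcomes without an
#'   entry get the default mild left-right gradient.
#' @param lesion_volume_range_ml c(lo, hi) in ml.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, outcome_names = c("mRS_day90", "BI_day360",
                                                   "NIHSS_admission"),
                        coupling = list(),
                        lesion_volume_range_ml = c(5, 40), seed = 1L) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (!length(outcome_names)) stop("outcome_names must not be empty")
  for (cp in coupling) {
    if (!is.function(cp$fn)) stop("each coupling needs a function `fn`")
    if (is.null(cp$noise_sd) || cp$noise_sd < 0)
      stop("each coupling needs noise_sd >= 0")
  }
  structure(list(n_cases = as.integer(n_cases), outcome_names = outcome_names,
                 coupling = coupling,
                 lesion_volume_range_ml = lesion_volume_range_ml,
                 seed = as.integer(seed)), class = "cohort_spec")
}

default_coupling <- function(name) {
  fns <- list(
    mRS_day90 = function(c, v) 3 + 0.025 * c[1] + 0.04 * (v - 20),
    BI_day360 = function(c, v) 70 - 0.8 * (v - 20) - 0.15 * c[2],
    NIHSS_admission = function(c, v) 8 + 0.3 * (v - 20) + 0.03 * c[3],
    NIHSS_day7 = function(c, v) 6 + 0.28 * (v - 20))
  fn <- fns[[name]]
  if (is.null(fn)) fn <- function(c, v) 3 + 0.025 * c[1]
  list(fn = fn, noise_sd = 0.3)
}

#' Generate a synthetic stroke cohort in the normalized space
#'
#' Each case receives a spherical lesion inside the atlas-space brain, its
#' contour set, and outcome variables computed as `coupling(centroid, volume)
#' + noise`. The stored variables include the lesion centroid and volume so
#' couplings can be re-derived exactly. Reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param grid optional `vol3d` prototype for the lesion masks (defaults to
#'   the atlas grid).
#' @return list of [case_record()] objects.
#' @export
make_cohort <- function(spec, grid = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  sp <- atlas_space()
  if (is.null(grid))
    grid <- vol3d(array(0L, sp$shape), sp$spacing, sp$origin)
  set.seed(spec$seed)
  bc <- sp$brain_center; B <- sp$brain_semi
  cases <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    vol_ml <- stats::runif(1, spec$lesion_volume_range_ml[1],
                           spec$lesion_volume_range_ml[2])
    r <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
    # rejection-sample a centre keeping the sphere inside the brain
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      ctr <- bc + u * (B - r - 2)
      if (sum(((ctr - bc) / (B - r))^2) < 1) break
    }
    mask <- lesion_sphere_mask(grid, ctr, r)
    idx <- which(mask$data != 0, arr.ind = TRUE)
    w <- index_to_world(mask, idx)
    centroid <- colMeans(w)
    volume_ml <- nrow(idx) * voxel_ml(mask)
    vars <- list(centroid_x = centroid[1], centroid_y = centroid[2],
                 centroid_z = centroid[3], infarct_volume_ml = volume_ml)
    for (nm in unique(c(spec$outcome_names, "NIHSS_admission", "NIHSS_day7"))) {
      cp <- spec$coupling[[nm]]
      if (is.null(cp)) cp <- default_coupling(nm)
      vars[[nm]] <- cp$fn(centroid, volume_ml) +
        if (cp$noise_sd > 0) stats::rnorm(1, 0, cp$noise_sd) else 0
    }
    cases[[i]] <- case_record(sprintf("case_%03d", i),
                              contours_from_mask(mask), vars,
                              to_psa = "identity")
  }
  cases
}

lesion_sphere_mask <- function(grid, center, radius) {
  pts <- grid_points(grid)
  m <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
       (pts[, 3] - center[3])^2 <= radius^2
  vol_like(grid, array(as.integer(m), dim(grid$data)))
}

#' Write / read a cohort's variables as a TSV case table
#' @param cases list of [case_record()].
#' @param path TSV path.
#' @export
write_case_table <- function(cases, path) {
  rows <- lapply(cases, function(cs)
    cbind(data.frame(case_id = cs$id), as.data.frame(cs$variables)))
  write_table_tsv(do.call(rbind, rows), path)
}
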