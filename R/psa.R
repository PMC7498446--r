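#' Probabilistic stroke atlas (PSA) map
#'
#' One aggregated 3D volume per clinical parameter plus a per-voxel coverage
#' count (number of contributing cases). The aggregate is zero wherever
#' coverage is zero.
#'
#' @param parameter parameter name.
#' @param aggregate `vol3d` of aggregated values in PSA space.
#' @param coverage `vol3d` of contributing-case counts.
#' @param n_cases number of cases aggregated.
#' @param scheme aggregation scheme id.
#' @return object of class `psa_map`.
#' @export
psa_map <- function(parameter, aggregate, coverage, n_cases, scheme) {
  stopifnot_vol(aggregate, "aggregate"); stopifnot_vol(coverage, "coverage")
  if (!same_grid(aggregate, coverage)) stop("grid mismatch")
  if (max(coverage$data) > n_cases) stop("coverage cannot exceed n_cases")
  if (any(aggregate$data[coverage$data == 0] != 0))
    stop("aggregate must be 0 where coverage is 0")
  structure(list(parameter = parameter, aggregate = aggregate,
                 coverage = coverage, n_cases = n_cases, scheme = scheme),
            class = "psa_map")
}

#' @export
print.psa_map <- function(x, ...) {
  cov <- x$coverage$data
  cat(sprintf("<psa_map> %s (%s over %d cases): %d covered voxel(s), max coverage %d\n",
              x$parameter, x$scheme, x$n_cases, sum(cov > 0), max(cov)))
  invisible(x)
}

#' Registered PSA aggregation schemes
#'
#' Eight voxelwise schemes over the contributing cases' parameter values:
#' `mean_global_n` (sum divided by the total case count, the literal
#' pseudocode reading), `mean_coverage` (sum divided by per-voxel coverage),
#' `median`, `trimmed_mean` (20% trimmed), `min`, `max`, `size_weighted_mean`
#' (weights inversely proportional to each case's lesion volume) and `sum`.
#'
#' @return character vector of scheme ids.
#' @export
psa_schemes <- function() c("mean_global_n", "mean_coverage", "median",
                            "trimmed_mean", "min", "max",
                            "size_weighted_mean", "sum")

#' Build a probabilistic stroke atlas for one parameter
#'
#' For each case, the lesion contour set is normalized into PSA space and the
#' case's parameter value aggregated into every voxel of its normalized ROI;
#' the aggregate is then reduced per voxel according to the scheme.
#'
#' @param cases list of [case_record()].
#' @param parameter variable name present in every case.
#' @param scheme one of [psa_schemes()].
#' @param space optional grid prototype `vol3d` (defaults to the atlas grid).
#' @return a [psa_map()].
#' @export
build_psa <- function(cases, parameter, scheme = "mean_coverage", space = NULL) {
  if (!length(cases)) stop("need at least one case")
  scheme <- match.arg(scheme, psa_schemes())
  if (is.null(space)) {
    sp <- atlas_space()
    space <- vol3d(array(0, sp$shape), sp$spacing, sp$origin)
  }
  rois <- lapply(cases, function(cs) {
    if (!inherits(cs, "case_record")) stop("cases must be case_record objects")
    which(normalize_case(cs, space)$data != 0)
  })
  vals <- vapply(cases, function(cs) {
    v <- cs$variables[[parameter]]
    if (is.null(v) || !is.finite(as.numeric(v)))
      stop("case ", cs$id, " is missing parameter '", parameter, "'")
    as.numeric(v)
  }, 0)
  psa_from_rois(parameter, rois, vals, scheme, space, voxel_ml(space))
}

# core sparse aggregation: rois is a list of voxel-index vectors
psa_from_rois <- function(parameter, rois, vals, scheme, space, vml) {
  n <- length(rois)
  vox <- unlist(rois, use.names = FALSE)
  val <- rep(vals, lengths(rois))
  d <- dim(space$data)
  cov <- tabulate(vox, prod(d))
  agg <- numeric(prod(d))
  if (scheme %in% c("mean_global_n", "mean_coverage", "sum")) {
    sums <- rowsum(val, vox)
    s <- numeric(prod(d))
    s[as.integer(rownames(sums))] <- sums[, 1]
    agg <- switch(scheme,
                  mean_global_n = s / n,
                  mean_coverage = ifelse(cov > 0, s / pmax(cov, 1L), 0),
                  sum = s)
  } else if (scheme == "size_weighted_mean") {
    wt <- rep(1 / pmax(lengths(rois) * vml, 1e-9), lengths(rois))
    sw <- rowsum(val * wt, vox); w <- rowsum(wt, vox)
    agg[as.integer(rownames(sw))] <- sw[, 1] / w[, 1]
  } else {
    f <- switch(scheme,
                median = stats::median,
                trimmed_mean = function(x) mean(x, trim = 0.2),
                min = min, max = max)
    grp <- split(val, vox)
    agg[as.integer(names(grp))] <- vapply(grp, f, 0)
  }
  agg[cov == 0] <- 0
  psa_map(parameter, vol_like(space, array(agg, d)),
          vol_like(space, array(as.integer(cov), d)), n, scheme)
}

#' Normalize a case's lesion into PSA space
#'
#' Rasterizes the contour set and maps it into the normalized space: identity
#' for cohorts generated there, the inverse of a stored atlas-to-scan
#' transform when one is attached, or the full ellipse-mapping pipeline on
#' the case's scan otherwise.
#'
#' @param case a [case_record()].
#' @param space `vol3d` prototype of the PSA grid.
#' @param bundle atlas bundle for the pipeline path (defaults to the
#'   simplified atlas).
#' @return binary `vol3d` lesion mask on the PSA grid.
#' @export
normalize_case <- function(case, space = NULL, bundle = NULL) {
  if (!inherits(case, "case_record")) stop("`case` must be a case_record")
  if (!length(case$lesion_contours$slices)) stop("empty contours")
  if (is.null(space)) {
    sp <- atlas_space()
    space <- vol3d(array(0, sp$shape), sp$spacing, sp$origin)
  }
  mask <- mask_from_contours(case$lesion_contours)
  tp <- case$to_psa
  if (is.null(tp)) {
    if (is.null(case$scan)) stop("case ", case$id,
                                 " has neither a transform nor a scan")
    if (is.null(bundle)) bundle <- build_simplified_atlas()
    tp <- individualize_atlas(bundle, case$scan)$transform
  }
  if (identical(tp, "identity")) return(resample_onto(mask, space, nearest = TRUE))
  if (!inherits(tp, "pwl_transform")) stop("invalid normalization transform")
  # tp maps atlas space -> scan space; pull the mask back onto the PSA grid
  pts <- apply_to_points_ext(tp, grid_points(space))
  vol_like(space, array(as.integer(sample_nearest(mask, pts, outside = 0L)),
                        dim(space$data)))
}

#' Select comparable cases for a constrained PSA instance
#'
#' For each constraint variable the cohort's value range (excluding the
#' target) is split into `n_ranges` quantile bins (half-open); cases falling
#' in the same bin as the target are kept. The target itself is always
#' excluded (leave-one-out).
#'
#' @param cases list of [case_record()].
#' @param target_case the case to predict (excluded from the result).
#' @param constraints character vector of variable names, or a list of
#'   `list(variable =, n_ranges =)`.
#' @param n_ranges default bin count per variable (4).
#' @return list of cases.
#' @export
constrain_cases <- function(cases, target_case, constraints = character(),
                            n_ranges = 4L) {
  ids <- vapply(cases, function(cs) cs$id, "")
  loo <- ids != target_case$id
  keep <- loo
  if (is.character(constraints))
    constraints <- lapply(constraints, function(v) list(variable = v,
                                                        n_ranges = n_ranges))
  for (con in constraints) {
    v <- con$variable
    nr <- if (is.null(con$n_ranges)) n_ranges else con$n_ranges
    vals <- vapply(cases, function(cs) {
      x <- cs$variables[[v]]
      if (is.null(x)) stop("variable '", v, "' missing in case ", cs$id)
      as.numeric(x)
    }, 0)
    tv <- target_case$variables[[v]]
    if (is.null(tv)) stop("variable '", v, "' missing in the target case")
    # range boundaries always come from the full cohort minus the target,
    # not from the running subset
    qs <- stats::quantile(vals[loo], probs = seq(0, 1, length.out = nr + 1L),
                          names = FALSE)
    qs[1] <- -Inf; qs[nr + 1L] <- Inf
    bin <- findInterval(as.numeric(tv), qs, rightmost.closed = FALSE,
                        left.open = FALSE)
    bin <- min(max(bin, 1L), nr)
    vb <- findInterval(vals, qs)
    vb <- pmin(pmax(vb, 1L), nr)
    keep <- keep & vb == bin
  }
  if (!any(keep)) stop("no comparable cases under the given constraints")
  cases[keep]
}

#' Read a predicted parameter from a PSA within an ROI
#'
#' Statistics over the PSA values at ROI voxels with positive coverage.
#'
#' @param psa a [psa_map()].
#' @param roi_mask binary `vol3d` on the PSA grid.
#' @return object of class `psa_prediction`: mean, sd (population),
#'   percentiles 25/50/75 and the number of voxels read.
#' @export
predict_psa <- function(psa, roi_mask) {
  if (!inherits(psa, "psa_map")) stop("`psa` must be a psa_map")
  stopifnot_vol(roi_mask, "roi_mask")
  if (!same_grid(psa$aggregate, roi_mask)) stop("grid mismatch")
  sel <- roi_mask$data != 0 & psa$coverage$data > 0
  if (!any(sel)) stop("ROI has no covered voxels in the PSA")
  x <- psa$aggregate$data[sel]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(parameter = psa$parameter, mean = mean(x),
                 sd = sqrt(mean((x - mean(x))^2)),
                 p25 = q[1], p50 = q[2], p75 = q[3],
                 n_voxels = sum(sel)), class = "psa_prediction")
}

#' @export
print.psa_prediction <- function(x, ...) {
  cat(sprintf("<psa_prediction> %s: mean %.3f, sd %.3f, p25/50/75 %.3f/%.3f/%.3f (%d voxels)\n",
              x$parameter, x$mean, x$sd, x$p25, x$p50, x$p75, x$n_voxels))
  invisible(x)
}

#' Incrementally add a case to a mean-coverage PSA
#'
#' For averaging aggregations the atlas extends incrementally: the per-voxel
#' sums are updated with the new case and re-divided, which equals a rebuild
#' from scratch.
#'
#' @param psa a `psa_map` built with scheme `mean_coverage`.
#' @param case a [case_record()] carrying the PSA parameter.
#' @return updated [psa_map()].
#' @export
psa_add_case <- function(psa, case) {
  if (!identical(psa$scheme, "mean_coverage"))
    stop("incremental update is defined for the mean_coverage scheme")
  v <- case$variables[[psa$parameter]]
  if (is.null(v)) stop("case ", case$id, " is missing parameter '",
                       psa$parameter, "'")
  m <- normalize_case(case, psa$aggregate)
  sel <- m$data != 0
  d <- dim(psa$aggregate$data)
  s <- psa$aggregate$data * psa$coverage$data
  s[sel] <- s[sel] + as.numeric(v)
  cov <- as.vector(psa$coverage$data) + as.integer(sel)
  agg <- ifelse(cov > 0, as.vector(s) / pmax(cov, 1L), 0)
  psa_map(psa$parameter, vol_like(psa$aggregate, array(agg, d)),
          vol_like(psa$coverage, array(as.integer(cov), d)),
          psa$n_cases + 1L, psa$scheme)
}

#' Leave-one-out evaluation of PSA outcome prediction
#'
#' Each case is predicted from the PSA built on the remaining cases
#' (optionally constrained to comparable cases); the error is the absolute
#' difference between the predicted (ROI mean) and actual value.
#'
#' @param cases list of [case_record()] (>= 3).
#' @param outcome_params character vector of parameters to predict.
#' @param scheme aggregation scheme.
#' @param constraints constraint specification for [constrain_cases()].
#' @param space optional PSA grid prototype.
#' @return object of class `psa_loo`: per-case error data frame, `mae` per
#'   parameter and `overall_mae`. Per-case failures are recorded, not fatal.
#' @export
loo_evaluate <- function(cases, outcome_params, scheme = "mean_coverage",
                         constraints = character(), space = NULL) {
  if (length(cases) < 3L) stop("leave-one-out needs at least 3 cases")
  if (is.null(space)) {
    sp <- atlas_space()
    space <- vol3d(array(0, sp$shape), sp$spacing, sp$origin)
  }
  # normalize every lesion once; folds reuse the sparse ROIs
  rois <- lapply(cases, function(cs) which(normalize_case(cs, space)$data != 0))
  ids <- vapply(cases, function(cs) cs$id, "")
  vml <- voxel_ml(space)
  rows <- list()
  for (i in seq_along(cases)) {
    target <- cases[[i]]
    roi_mask <- vol_like(space, array(0L, dim(space$data)))
    roi_mask$data[rois[[i]]] <- 1L
    for (par in outcome_params) {
      res <- tryCatch({
        train <- constrain_cases(cases, target, constraints)
        sel <- match(vapply(train, function(cs) cs$id, ""), ids)
        vals <- vapply(train, function(cs) as.numeric(cs$variables[[par]]), 0)
        psa <- psa_from_rois(par, rois[sel], vals, scheme, space, vml)
        pred <- predict_psa(psa, roi_mask)
        actual <- as.numeric(target$variables[[par]])
        data.frame(case_id = target$id, parameter = par,
                   predicted = pred$mean, actual = actual,
                   abs_error = abs(pred$mean - actual),
                   n_train = length(train), error_msg = NA_character_)
      }, error = function(e)
        data.frame(case_id = target$id, parameter = par,
                   predicted = NA_real_, actual = NA_real_,
                   abs_error = NA_real_, n_train = NA_integer_,
                   error_msg = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  mae <- tapply(tab$abs_error, tab$parameter, mean, na.rm = TRUE)
  structure(list(errors = tab, mae = mae,
                 overall_mae = mean(tab$abs_error, na.rm = TRUE)),
            class = "psa_loo")
}

#' @export
print.psa_loo <- function(x, ...) {
  cat(sprintf("<psa_loo> overall MAE %.4f over %d prediction(s)\n",
              x$overall_mae, nrow(x$errors)))
  print(round(x$mae, 4))
  invisible(x)
}

#' Enumerate a PSA study design
#'
#' Counts the PSA instances implied by a design: per case, one instance per
#' aggregation scheme and per combination of selection-variable ranges;
#' multiplied by the number of predicted parameters and cases for the total,
#' and by the remaining cases for the number of case processings under
#' leave-one-out.
#'
#' @param n_aggregations number of aggregation schemes.
#' @param range_counts integer vector: ranges per selection variable.
#' @param n_outcomes number of predicted parameters.
#' @param n_cases cohort size.
#' @return list: `instances_per_case`, `total_instances`,
#'   `total_case_processings`.
#' @export
enumerate_design <- function(n_aggregations, range_counts, n_outcomes, n_cases) {
  if (n_aggregations < 1 || n_outcomes < 1 || n_cases < 1 ||
      any(range_counts < 1)) stop("all design counts must be >= 1")
  ipc <- n_aggregations * prod(range_counts)
  total <- ipc * n_outcomes * n_cases
  list(instances_per_case = ipc,
       total_instances = total,
       total_case_processings = total * (n_cases - 1))
}

#' Write a PSA map as paired NIfTI volumes plus JSON metadata
#' @param psa a [psa_map()].
#' @param prefix output path prefix.
#' @export
write_psa <- function(psa, prefix) {
  write_volume(psa$aggregate, paste0(prefix, "_aggregate.nii.gz"))
  write_volume(psa$coverage, paste0(prefix, "_coverage.nii.gz"))
  jsonlite::write_json(list(parameter = psa$parameter, scheme = psa$scheme,
                            n_cases = psa$n_cases),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}
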