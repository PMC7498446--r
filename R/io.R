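#' Read / write 3D volumes as NIfTI-1
#'
#' Volumes are reoriented to the canonical right/anterior/superior axes on
#' load (a message notes any flip or permutation); only axis-aligned grids
#' are represented, so the world origin and spacing come from the sform/qform
#' after reorientation.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return a `vol3d`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("only 3D volumes are supported")
  orc <- RNifti::orientation(img)
  if (!identical(orc, "RAS")) {
    message("reorienting volume from ", orc, " to RAS: ", path)
    RNifti::orientation(img) <- "RAS"
  }
  xf <- RNifti::xform(img)
  sp <- RNifti::pixdim(img)[1:3]
  vol3d(array(as.numeric(img), dim(img)), sp, as.numeric(xf[1:3, 4]))
}

#' @rdname read_volume
#' @param v a `vol3d`.
#' @export
write_volume <- function(v, path) {
  stopifnot_vol(v)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  m <- diag(4); diag(m)[1:3] <- v$spacing; m[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write case tables as TSV
#'
#' One row per case, one column per variable; `case_id` is mandatory.
#'
#' @param path TSV file path.
#' @param required character vector of column names that must be present.
#' @return data frame.
#' @export
read_table_tsv <- function(path, required = "case_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_table_tsv
#' @param df data frame.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
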