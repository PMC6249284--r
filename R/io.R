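#' Read and write pipeline tables as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a 3D map or 4D run as NIfTI-1
#'
#' @param x 3D array, or voxels x volumes matrix with `grid` supplied.
#' @param path output path (`.nii`).
#' @param grid a [make_grid()] providing the affine.
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(x, path, grid) {
  if (is.matrix(x)) x <- array(x, c(grid$shape, ncol(x)))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(grid$voxel_mm, 3)
  aff <- grid$affine
  # RNifti uses 0-based voxel indices; shift the origin accordingly
  aff0 <- aff
  aff0[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  RNifti::qform(img) <- structure(aff0, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI path.
#' @return Numeric array (attributes stripped).
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write a censor mask as a one-column 0/1 TSV
#'
#' @param mask a `censor_mask` (or logical vector).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_censor_tsv <- function(mask, path) {
  keep <- if (inherits(mask, "censor_mask")) unlist(mask$keep) else mask
  utils::write.table(data.frame(keep = as.integer(keep)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a model or QC report to JSON
#'
#' @param x list-like object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
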