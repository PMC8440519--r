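#' Write volumes as NIfTI files
#'
#' @param volumes list of 3-D arrays.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_nifti_volumes <- function(volumes, dir, prefix = "vol") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(volumes), function(i) {
    p <- file.path(dir, sprintf("%s%03d.nii", prefix, i))
    RNifti::writeNifti(RNifti::asNifti(volumes[[i]]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read NIfTI volumes as plain arrays
#'
#' @param paths NIfTI file paths.
#' @return list of numeric arrays.
#' @export
read_nifti_volumes <- function(paths) {
  lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim = dim(v))
  })
}
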