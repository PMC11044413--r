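## NIfTI I/O: thin wrappers around RNifti keeping the input affine.

#' Read a DWI volume (NIfTI)
#'
#' @param path Path to a 3-D or 4-D NIfTI file (.nii or .nii.gz).
#' @return The image as a plain numeric array with the `niftiImage` kept in
#'   attribute `reference` for header-preserving writes.
#' @export
read_dwi_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "reference") <- img
  arr
}

#' Read a binary ROI mask (NIfTI)
#'
#' @param path Path to a 3-D NIfTI mask; any non-zero voxel is in the ROI.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path) {
  arr <- read_dwi_volume(path)
  if (length(dim(arr)) != 3L) stop("mask must be 3-D: ", path)
  m <- array(arr != 0, dim = dim(arr))
  attr(m, "reference") <- attr(arr, "reference")
  m
}

#' Write parameter maps as NIfTI files
#'
#' One float32 file per parameter, named `<prefix>_<parameter>.nii.gz`, with
#' the affine of `reference` when given.
#'
#' @param maps Named list of 3-D arrays, as returned by [fit_volume()].
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name prefix, typically the model name.
#' @param reference Optional `niftiImage` (or array with a `reference`
#'   attribute) providing header/affine.
#' @return Invisibly, the vector of written paths.
#' @export
write_parameter_maps <- function(maps, out_dir, prefix = "map",
                                 reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(attr(reference, "reference")))
    reference <- attr(reference, "reference")
  paths <- character(0)
  for (p in names(maps)) {
    path <- file.path(out_dir, paste0(prefix, "_", p, ".nii.gz"))
    img <- if (is.null(reference)) {
      RNifti::asNifti(maps[[p]], datatype = "float")
    } else {
      RNifti::asNifti(maps[[p]], reference = reference, datatype = "float")
    }
    RNifti::writeNifti(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
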