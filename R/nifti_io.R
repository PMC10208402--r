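# NIfTI-1 volume I/O: thin wrappers around RNifti plus grid/contract checks.

#' Read a 4D diffusion-weighted volume with its gradient table
#'
#' @param nii_path NIfTI-1 file (.nii or .nii.gz) with one volume per
#'   gradient table entry.
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @param mask_path Optional 3D binary mask on the same grid; default is an
#'   all-TRUE mask.
#' @param b0_threshold See [gradient_scheme()].
#' @return A list of class `dwi_volume`: `data` (4D array), `scheme`,
#'   `mask` (3D logical), `affine` (4 x 4), `voxel_size` (mm), `dims`.
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path, mask_path = NULL,
                     b0_threshold = 50) {
  img <- RNifti::readNifti(nii_path)
  data <- unclass(img)[, , , , drop = FALSE]
  if (length(dim(data)) != 4L)
    stop("expected a 4D diffusion volume, got ", length(dim(data)), "D")
  scheme <- read_gradient_table(bval_path, bvec_path, b0_threshold)
  if (dim(data)[4L] != length(scheme$bvals))
    stop("volume count (", dim(data)[4L], ") does not match gradient table (",
         length(scheme$bvals), ")")
  dims <- dim(data)[1:3]
  mask <- if (is.null(mask_path)) array(TRUE, dims) else {
    m <- unclass(RNifti::readNifti(mask_path))
    if (!identical(dim(m)[1:3], dims))
      stop("grid mismatch: mask dims (", paste(dim(m)[1:3], collapse = "x"),
           ") differ from data dims (", paste(dims, collapse = "x"), ")")
    array(m != 0, dims)
  }
  aff <- structure(RNifti::xform(img), class = NULL, code = NULL,
                   imagedim = NULL)
  structure(list(data = data, scheme = scheme, mask = mask,
                 affine = aff, voxel_size = sqrt(colSums(aff[1:3, 1:3]^2)),
                 dims = dims),
            class = "dwi_volume")
}

#' Read a 3D scalar map
#'
#' @param path NIfTI-1 file.
#' @return 3D array with attributes `affine` and `voxel_size`.
#' @export
read_scalar_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- unclass(img)[, , , drop = FALSE]
  if (length(dim(arr)) != 3L) stop("expected a 3D scalar map")
  out <- array(as.numeric(arr), dim(arr))
  aff <- structure(RNifti::xform(img), class = NULL, code = NULL,
                   imagedim = NULL)
  attr(out, "affine") <- aff
  attr(out, "voxel_size") <- sqrt(colSums(aff[1:3, 1:3]^2))
  out
}

#' Write a 3D scalar map as NIfTI-1
#'
#' Values are stored as 64-bit floats so that a write/read round trip is
#' exact; the affine is preserved exactly.
#'
#' @param map 3D numeric array.
#' @param path Output path (.nii or .nii.gz).
#' @param affine 4 x 4 voxel-to-world matrix (default identity).
#' @return Invisibly, `path`.
#' @export
write_scalar_map <- function(map, path, affine = NULL) {
  if (length(dim(map)) != 3L) stop("map must be a 3D array")
  if (is.null(affine)) affine <- attr(map, "affine")
  if (is.null(affine)) affine <- diag(4)
  img <- RNifti::asNifti(array(as.numeric(map), dim(map)),
                         datatype = "double")
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 4D volume stack as NIfTI-1
#'
#' @param data 4D numeric array.
#' @param path Output path.
#' @param affine 4 x 4 voxel-to-world matrix (default identity).
#' @return Invisibly, `path`.
#' @export
write_volume4d <- function(data, path, affine = diag(4)) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  img <- RNifti::asNifti(array(as.numeric(data), dim(data)),
                         datatype = "double")
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer ROI label volume
#'
#' @param path NIfTI-1 file with integer labels, 0 = background.
#' @return 3D integer array with attribute `affine`.
#' @export
read_labels <- function(path) {
  arr <- read_scalar_map(path)
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("label volume is not integer-valued")
  out <- array(as.integer(round(arr)), dim(arr))
  attr(out, "affine") <- attr(arr, "affine")
  out
}

# Grid compatibility check used by the ROI pipeline.
check_same_grid <- function(a_dims, b_dims, what = "volumes") {
  if (!identical(as.integer(a_dims), as.integer(b_dims)))
    stop("grid mismatch between ", what, ": ",
         paste(a_dims, collapse = "x"), " vs ", paste(b_dims, collapse = "x"))
  invisible(TRUE)
}
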