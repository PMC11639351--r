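# NIfTI-1 I/O via RNifti. On disk volumes are (X, Y, Z) or (X, Y, Z, C);
# in memory images are channel-first (C, X, Y, Z).

#' Load a NIfTI volume as a channel-first array
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return (C, X, Y, Z) numeric array with attributes `spacing` (voxel size in
#'   mm) and `affine` (4x4 voxel-to-world matrix). 3D files become C = 1.
#' @export
loadVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 3L) arr <- array(as.numeric(arr), dim = c(1L, dim(arr)))
  else if (nd == 4L) arr <- aperm(array(as.numeric(arr), dim = dim(arr)), c(4L, 1L, 2L, 3L))
  else stop("expected a 3D or 4D NIfTI volume, got ", nd, " dims", call. = FALSE)
  structure(arr,
            spacing = as.numeric(RNifti::pixdim(img))[1:3],
            affine = structure(as.vector(RNifti::xform(img)), dim = c(4L, 4L)))
}

#' Load a NIfTI label map
#'
#' @param path a `.nii` or `.nii.gz` file holding an integer 3D label volume.
#' @param image_shape optional (X, Y, Z) shape the labels must match.
#' @return (X, Y, Z) integer array.
#' @export
loadLabels <- function(path, image_shape = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop("label file must be 3D, got ", length(dim(arr)), " dims", call. = FALSE)
  if (!is.null(image_shape) && !identical(dim(arr), as.integer(image_shape)))
    stop("label shape (", paste(dim(arr), collapse = "x"),
         ") does not match image (", paste(image_shape, collapse = "x"), ")", call. = FALSE)
  array(as.integer(round(arr)), dim = dim(arr))
}

#' Save a volume, label map or prediction as NIfTI
#'
#' @param path output `.nii` or `.nii.gz` path.
#' @param x a (C, X, Y, Z) image/probability array (written as 4D X,Y,Z,C) or
#'   a 3D label array.
#' @param spacing voxel spacing in mm (default the 1 mm isotropic convention).
#' @return the path, invisibly.
#' @export
savePrediction <- function(path, x, spacing = c(1, 1, 1)) {
  if (length(dim(x)) == 4L) x <- aperm(x, c(2L, 3L, 4L, 1L))
  attributes(x)[setdiff(names(attributes(x)), "dim")] <- NULL
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname savePrediction
#' @export
saveVolume <- savePrediction
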