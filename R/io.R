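#' Read a binary mask from a NIfTI file
#'
#' Reads a 3D (or single-slice 2D) NIfTI volume, binarises it (any nonzero
#' value is in-mask) and takes the voxel spacing from the header `pixdim`.
#' The orientation/affine information of the header is recorded as an
#' attribute for provenance but is not used by any metric: metrics depend
#' only on the shared voxel grid, so truth and prediction must already live
#' on the same grid.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [binary_mask()] with attribute `source` (the path).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) == 2) {
    arr <- array(as.numeric(img), dim = c(d, 1L))
  } else if (length(d) == 3) {
    arr <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 3D volume; ", path, " has shape ",
         paste(d, collapse = " x "))
  }
  sp <- RNifti::pixdim(img)
  sp <- c(sp, 1, 1)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("invalid voxel spacing in NIfTI header of ", path, ": (",
         paste(format(sp), collapse = ", "), ")")
  }
  out <- binary_mask(arr != 0, sp)
  attr(out, "source") <- path
  attr(out, "orientation") <- tryCatch(RNifti::orientation(img),
                                       error = function(e) NA_character_)
  out
}

#' Write a binary mask to a NIfTI file
#'
#' Voxels are written as 0/1 integers with the mask spacing in the header.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  attr(arr, "pixdim") <- mask$spacing
  img <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}
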