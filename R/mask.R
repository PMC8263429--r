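#' Construct a binary mask with physical voxel spacing
#'
#' A `binary_mask` is the unit of comparison for every metric in the package:
#' a 3D voxel grid of in/out labels together with the physical size of a voxel
#' along each axis (mm). 2D inputs are accepted and promoted to shape
#' `c(nx, ny, 1)`, so slice-wise illustrations work with the same code paths.
#'
#' Coordinates are voxel indices (1-based, R convention); the physical
#' position of a voxel centre is `(index - 1) * spacing` componentwise. Every
#' metric depends only on relative distances, so the origin convention is
#' immaterial.
#'
#' @param data A logical or numeric 2D/3D array. Numeric values are binarised:
#'   nonzero means in-mask.
#' @param spacing Positive numeric vector of voxel dimensions in mm, length 3
#'   (or length 2 for 2D input, in which case the third spacing is 1).
#' @return An object of class `binary_mask` with elements `data` (logical 3D
#'   array) and `spacing` (numeric length 3).
#' @examples
#' m <- binary_mask(array(c(1, 0, 0, 1), dim = c(2, 2, 1)), spacing = c(1, 1, 2))
#' n_voxels(m)
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) && !is.matrix(data)) {
    stop("`data` must be a 2D or 3D array")
  }
  d <- dim(data)
  if (length(d) == 2) {
    dim(data) <- c(d, 1L)
    if (length(spacing) == 2) spacing <- c(spacing, 1)
    d <- dim(data)
  }
  if (length(d) != 3) {
    stop("`data` must be 2D or 3D; got an array of shape ",
         paste(d, collapse = " x "))
  }
  if (length(spacing) != 3 || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite numbers (mm)")
  }
  storage <- data
  if (!is.logical(storage)) {
    storage <- array(as.logical(storage != 0), dim = d)
  }
  if (anyNA(storage)) stop("mask voxels must not be NA")
  structure(list(data = storage, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, ", sum(x$data), " in-mask\n", sep = "")
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' Number of in-mask voxels
#' @param mask A [binary_mask()].
#' @return Integer count of in-mask voxels.
#' @export
n_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data)
}

#' Physical volume of a mask in mm^3
#' @param mask A [binary_mask()].
#' @return Voxel count times the single-voxel volume, in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  n_voxels(mask) * prod(mask$spacing)
}

voxel_volume <- function(mask) prod(mask$spacing)

is_empty_mask <- function(mask) !any(mask$data)

#' Check that two masks share grid shape and spacing
#'
#' All pairwise metrics require the ground truth and the prediction to live on
#' the same voxel grid. Spacing is compared with a small relative tolerance to
#' absorb header rounding in files.
#'
#' @param a,b [binary_mask()] objects.
#' @return `TRUE` invisibly; otherwise an error describing both geometries.
#' @export
check_same_geometry <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$data), dim(b$data))) {
    stop("mask shapes differ: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  }
  if (max(abs(a$spacing - b$spacing) / a$spacing) > 1e-6) {
    stop("mask spacings differ: (", paste(format(a$spacing), collapse = ", "),
         ") vs (", paste(format(b$spacing), collapse = ", "), ") mm")
  }
  invisible(TRUE)
}

#' Rebuild a single structure as a standalone mask
#'
#' @param structure A structure entry from [label_components()] (with `coords`
#'   and `label`).
#' @param template A [binary_mask()] supplying the grid shape and spacing.
#' @return A [binary_mask()] containing exactly the structure's voxels.
#' @export
structure_to_mask <- function(structure, template) {
  stopifnot(inherits(template, "binary_mask"))
  coords <- structure$coords
  d <- dim(template$data)
  if (nrow(coords) == 0) stop("structure has no voxels")
  if (any(coords < 1) || any(coords[, 1] > d[1]) || any(coords[, 2] > d[2]) ||
      any(coords[, 3] > d[3])) {
    stop("structure coordinates fall outside the template grid")
  }
  arr <- array(FALSE, dim = d)
  arr[coords] <- TRUE
  binary_mask(arr, template$spacing)
}

# Coordinates (1-based, n x 3 integer matrix) of in-mask voxels, in
# column-major scan order.
mask_coords <- function(mask) {
  which_arr <- which(mask$data)
  arrayInd(which_arr, dim(mask$data))
}
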