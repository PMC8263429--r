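#' Extract the boundary surface of a mask
#'
#' The boundary is the morphological inner boundary: every in-mask voxel with
#' at least one of its six face neighbours out-of-mask. Neighbours beyond the
#' grid count as out-of-mask, so in-mask voxels on the grid edge are boundary
#' voxels. This is the voxel-level surface from which all distance metrics are
#' computed; no sub-voxel (mesh) surface is constructed.
#'
#' @param mask A [binary_mask()].
#' @return An object of class `boundary_surface`: a list with `coords`
#'   (n x 3 matrix of 1-based voxel indices), `points` (n x 3 matrix of
#'   physical voxel-centre positions in mm, `(coords - 1) * spacing`), and
#'   `spacing`. An empty mask yields an empty surface.
#' @examples
#' cube <- binary_mask(array(1, c(5, 5, 5)))
#' nrow(extract_boundary(cube)$coords)  # 5^3 - 3^3 = 98
#' @export
extract_boundary <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  bnd <- inner_boundary(as.logical(mask$data), d)
  idx <- which(bnd)
  coords <- arrayInd(idx, d)
  points <- sweep(coords - 1, 2, mask$spacing, `*`)
  structure(list(coords = coords, points = points, spacing = mask$spacing),
            class = "boundary_surface")
}

#' @export
print.boundary_surface <- function(x, ...) {
  cat("<boundary_surface> ", nrow(x$coords), " boundary voxel(s)\n", sep = "")
  invisible(x)
}
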