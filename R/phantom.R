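#' Specify a multi-structure ellipsoid phantom
#'
#' A phantom emulates a multi-structure clinical delineation (a primary
#' tumour plus involved nodes) as a set of ellipsoids on a voxel grid.
#' Ellipsoids are used deliberately: every expected volume and overlap has an
#' analytic reference, which makes each metric testable without clinical
#' data.
#'
#' @param shape Integer triple — grid size in voxels.
#' @param spacing Positive numeric triple — voxel size in mm.
#' @param centers k x 3 matrix (or length-3 vector) of ellipsoid centres in
#'   mm (voxel-centre coordinates: voxel `i` sits at `(i - 1) * spacing`).
#' @param radii k x 3 matrix (or length-3 vector) of ellipsoid semi-axes in
#'   mm, all positive. A sphere has three equal semi-axes.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), centers, radii) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(spacing) == 3, all(spacing > 0))
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3, byrow = TRUE)
  if (is.null(dim(radii))) radii <- matrix(radii, ncol = 3, byrow = TRUE)
  centers <- as.matrix(centers)
  radii <- as.matrix(radii)
  if (nrow(centers) != nrow(radii)) {
    stop("`centers` and `radii` must describe the same number of structures")
  }
  if (nrow(radii) > 0 && any(radii <= 0)) stop("ellipsoid radii must be positive")
  extent <- (shape - 1) * spacing
  for (k in seq_len(nrow(centers))) {
    if (any(centers[k, ] - radii[k, ] < 0) ||
        any(centers[k, ] + radii[k, ] > extent)) {
      stop("structure ", k, " extends beyond the grid")
    }
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 centers = centers, radii = radii),
            class = "phantom_spec")
}

#' Render a phantom specification as a binary mask
#'
#' A voxel is in-mask iff its physical centre lies inside (or on) any of the
#' specified ellipsoids: \eqn{\sum_a ((p_a - c_a)/r_a)^2 \le 1}. Rendering is
#' deterministic — the same spec always yields a bit-identical mask. An empty
#' structure list renders an empty mask.
#'
#' @param spec A [phantom_spec()].
#' @return A [binary_mask()].
#' @examples
#' sp <- phantom_spec(c(16, 16, 16), c(1, 1, 1),
#'                    centers = c(7.5, 7.5, 7.5), radii = c(5, 5, 5))
#' n_voxels(render_phantom(sp))  # close to 4/3 * pi * 5^3
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  arr <- array(FALSE, dim = d)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spec$spacing[a])
  for (k in seq_len(nrow(spec$centers))) {
    cc <- spec$centers[k, ]
    rr <- spec$radii[k, ]
    # per-axis squared normalised offsets, combined by outer sums
    u <- ((ax[[1]] - cc[1]) / rr[1])^2
    v <- ((ax[[2]] - cc[2]) / rr[2])^2
    w <- ((ax[[3]] - cc[3]) / rr[3])^2
    q <- outer(outer(u, v, `+`), w, `+`)
    arr <- arr | (q <= 1)
  }
  binary_mask(arr, spec$spacing)
}

#' Generate a random multi-sphere phantom
#'
#' Draws `n_structures` non-touching spheres with radii uniform in
#' `radius_range`, placed uniformly on the grid, rejecting draws whose bounding
#' spheres come within `min_gap_mm` of each other so that component counts are
#' known by construction. Reproducible: the random stream is derived from
#' `seed` alone and the global RNG state is untouched.
#'
#' @param shape,spacing Grid geometry as in [phantom_spec()].
#' @param n_structures Number of spheres.
#' @param radius_range Length-2 numeric range of sphere radii (mm).
#' @param min_gap_mm Minimum surface-to-surface gap between spheres (mm).
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
random_phantom <- function(shape, spacing = c(1, 1, 1), n_structures = 3,
                           radius_range = c(4, 8), min_gap_mm = 3,
                           seed = 1L) {
  shape <- as.integer(shape)
  extent <- (shape - 1) * spacing
  centers <- matrix(NA_real_, 0, 3)
  radii <- matrix(NA_real_, 0, 3)
  with_local_seed(seed, {
    tries <- 0
    while (nrow(centers) < n_structures) {
      tries <- tries + 1
      if (tries > 1000 * n_structures) {
        stop("could not place ", n_structures,
             " non-touching spheres; grid too small for the radius range")
      }
      r <- stats::runif(1, radius_range[1], radius_range[2])
      if (any(extent < 2 * r)) next
      cc <- vapply(1:3, function(a) stats::runif(1, r, extent[a] - r),
                   numeric(1))
      ok <- TRUE
      for (k in seq_len(nrow(centers))) {
        if (sqrt(sum((cc - centers[k, ])^2)) <
            r + radii[k, 1] + min_gap_mm) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        centers <- rbind(centers, cc)
        radii <- rbind(radii, rep(r, 3))
      }
    }
  })
  phantom_spec(shape, spacing, centers, radii)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# any pre-existing global .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

shift_array <- function(arr, offset) {
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      src[[a]] <- seq_len(d[a] - o)
      dst[[a]] <- seq_len(d[a] - o) + o
    } else {
      src[[a]] <- seq_len(d[a] + o) - o
      dst[[a]] <- seq_len(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_once <- function(arr, connectivity = 6) {
  out <- arr
  offs <- neighbour_offset_list(connectivity)
  for (o in offs) out <- out | shift_array(arr, o)
  out
}

erode_once <- function(arr, connectivity = 6) {
  out <- arr
  offs <- neighbour_offset_list(connectivity)
  for (o in offs) {
    shifted <- shift_array(arr, o)
    # neighbours beyond the grid count as out-of-mask, consistent with the
    # boundary definition
    out <- out & shifted
  }
  out
}

neighbour_offset_list <- function(connectivity) {
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    o <- sum(abs(c(dx, dy, dz)))
    if (o == 0) next
    if (connectivity == 6 && o > 1) next
    if (connectivity == 18 && o > 2) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  offs
}

#' Apply a controlled perturbation to a mask
#'
#' Each perturbation maps a valid mask to a valid mask on the same grid with
#' a known qualitative metric signature, which is how the evaluation metrics
#' are exercised without clinical data:
#'
#' * `translate` — shift by an integer voxel `offset` (clipped at the grid
#'   edge); moves all surface distances, leaves volumes nearly unchanged.
#' * `dilate` / `erode` — `iterations` of face-neighbour morphological
#'   dilation/erosion; moves boundaries by about one voxel per iteration.
#' * `add_false_structure` — inserts an ellipsoid (`center`, `radii` in mm)
#'   that must be disjoint from (and not touching, under 26-connectivity) the
#'   existing mask; lowers structure-level PPV and inflates patient-wise
#'   distances while leaving sensitivity and structure-wise distances fixed.
#' * `delete_structure` — removes the component with label `structure`
#'   (under `connectivity`); lowers sensitivity when applied to a prediction's
#'   matched structure.
#' * `boundary_jitter` — independently toggles boundary-adjacent voxels with
#'   probability `amplitude` (seeded); roughens the surface.
#'
#' @param mask A [binary_mask()].
#' @param kind One of `"translate"`, `"dilate"`, `"erode"`,
#'   `"add_false_structure"`, `"delete_structure"`, `"boundary_jitter"`.
#' @param offset Integer voxel offset (translate).
#' @param iterations Positive integer (dilate/erode); default 1.
#' @param center,radii Ellipsoid centre and semi-axes in mm
#'   (add_false_structure).
#' @param structure Label of the component to delete (delete_structure).
#' @param amplitude Toggle probability in `[0, 1]` (boundary_jitter).
#' @param connectivity Connectivity used for `delete_structure`; default 26.
#' @param seed Integer seed for `boundary_jitter`; default 1.
#' @return A [binary_mask()] on the same grid.
#' @export
perturb <- function(mask, kind, offset = c(0, 0, 0), iterations = 1,
                    center = NULL, radii = NULL, structure = NULL,
                    amplitude = 0.1, connectivity = 26, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  kind <- match.arg(kind, c("translate", "dilate", "erode",
                            "add_false_structure", "delete_structure",
                            "boundary_jitter"))
  arr <- mask$data
  out <- switch(kind,
    translate = {
      offset <- as.integer(round(offset))
      stopifnot(length(offset) == 3)
      shift_array(arr, offset)
    },
    dilate = {
      for (i in seq_len(iterations)) arr <- dilate_once(arr)
      arr
    },
    erode = {
      for (i in seq_len(iterations)) arr <- erode_once(arr)
      arr
    },
    add_false_structure = {
      if (is.null(center) || is.null(radii)) {
        stop("add_false_structure requires `center` and `radii` (mm)")
      }
      blob <- render_phantom(phantom_spec(dim(arr), mask$spacing,
                                          center, radii))$data
      if (!any(blob)) stop("false structure renders to zero voxels")
      if (any(dilate_once(blob, 26) & arr)) {
        stop("false structure touches the existing mask; it must be disjoint")
      }
      arr | blob
    },
    delete_structure = {
      ss <- label_components(mask, connectivity)
      if (is.null(structure) || !structure %in% seq_along(ss$structures)) {
        stop("`structure` must be an existing component label (1..",
             length(ss$structures), ")")
      }
      arr[ss$structures[[structure]]$coords] <- FALSE
      arr
    },
    boundary_jitter = {
      stopifnot(amplitude >= 0, amplitude <= 1)
      inner <- inner_boundary(as.logical(arr), dim(arr))
      outer_shell <- dilate_once(arr) & !arr
      idx_in <- which(array(inner, dim(arr)))
      idx_out <- which(outer_shell)
      with_local_seed(seed, {
        drop <- idx_in[stats::runif(length(idx_in)) < amplitude]
        add <- idx_out[stats::runif(length(idx_out)) < amplitude]
        arr[drop] <- FALSE
        arr[add] <- TRUE
      })
      arr
    })
  binary_mask(out, mask$spacing)
}

#' Write / read a phantom specification as plain-text JSON
#'
#' Serialises the grid geometry and ellipsoid table so that demo and test
#' fixtures are reproducible from a small text file.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `write_phantom_spec` returns `path` invisibly; `read_phantom_spec`
#'   returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(list(shape = spec$shape, spacing = spec$spacing,
                            centers = spec$centers, radii = spec$radii),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @examples
#' demo <- system.file("extdata", "phantom_demo.json", package = "maskeval")
#' n_voxels(render_phantom(read_phantom_spec(demo)))
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- matrix(as.numeric(x$centers), ncol = 3)
  radii <- matrix(as.numeric(x$radii), ncol = 3)
  phantom_spec(x$shape, x$spacing, centers, radii)
}
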