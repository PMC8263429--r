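#' Directed boundary-to-boundary distance set
#'
#' For every boundary voxel of `source`, the smallest Euclidean distance (mm,
#' voxel centre to voxel centre, honouring anisotropic spacing) to any
#' boundary voxel of `reference`. The result is directed: one distance per
#' source boundary voxel, and swapping the arguments generally changes the
#' multiset. Surface summaries (HD95, ASD, MSD) are order statistics of this
#' multiset.
#'
#' @param source,reference `boundary_surface` objects from
#'   [extract_boundary()], or [binary_mask()]s (boundaries are extracted).
#' @return A numeric vector of distances (class `distance_set`), one per
#'   source boundary voxel.
#' @export
boundary_distances <- function(source, reference) {
  if (inherits(source, "binary_mask")) source <- extract_boundary(source)
  if (inherits(reference, "binary_mask")) reference <- extract_boundary(reference)
  stopifnot(inherits(source, "boundary_surface"),
            inherits(reference, "boundary_surface"))
  if (nrow(source$points) == 0) {
    stop("source boundary is empty; distances are undefined")
  }
  if (nrow(reference$points) == 0) {
    stop("reference boundary is empty; distances are undefined")
  }
  if (max(abs(source$spacing - reference$spacing) / source$spacing) > 1e-6) {
    stop("source and reference surfaces have different spacings")
  }
  d <- min_pair_dists(source$points, reference$points)
  class(d) <- c("distance_set", class(d))
  d
}

#' Summarise a distance multiset as HD95 / ASD / MSD
#'
#' `hd95_mm` is the 95th percentile (linear interpolation between order
#' statistics, [stats::quantile()] type 7 — pinned for reproducibility),
#' `asd_mm` the arithmetic mean and `msd_mm` the median of the distances.
#' HD95 captures the severity of the largest delineation errors while staying
#' robust to single outliers; ASD and MSD capture the typical boundary error.
#'
#' @param dset Nonempty numeric vector of distances (mm), e.g. from
#'   [boundary_distances()].
#' @return A `surface_summary` list: `hd95_mm`, `asd_mm`, `msd_mm`,
#'   `n_distances`.
#' @export
summarize_distances <- function(dset) {
  d <- as.numeric(dset)
  if (length(d) == 0) stop("distance set is empty; summaries are undefined")
  if (any(d < 0)) stop("distances must be nonnegative")
  structure(list(
    hd95_mm = unname(stats::quantile(d, 0.95, type = 7)),
    asd_mm = mean(d),
    msd_mm = unname(stats::median(d)),
    n_distances = length(d)
  ), class = "surface_summary")
}

na_surface_summary <- function() {
  structure(list(hd95_mm = NA_real_, asd_mm = NA_real_, msd_mm = NA_real_,
                 n_distances = 0L), class = "surface_summary")
}

#' @export
print.surface_summary <- function(x, ...) {
  cat("<surface_summary> HD95 ", format(x$hd95_mm), " mm, ASD ",
      format(x$asd_mm), " mm, MSD ", format(x$msd_mm), " mm (n = ",
      x$n_distances, ")\n", sep = "")
  invisible(x)
}

#' Patient-wise surface-distance summary
#'
#' Distances from the whole predicted-mask boundary to the whole ground-truth
#' boundary, summarised as HD95/ASD/MSD. This whole-mask variant deliberately
#' includes false-positive structures: a predicted blob far from the truth
#' contributes large distances, which is exactly the contamination the
#' structure-wise variant ([structurewise_surface()]) removes.
#'
#' @param truth,prediction [binary_mask()] objects on the same grid.
#' @param symmetric If `TRUE`, pool distances from both directions
#'   (prediction to truth and truth to prediction) before summarising. The
#'   default is the directed prediction-to-truth set.
#' @return A `surface_summary`; if either mask is empty, a summary of `NA`s
#'   with attribute `flag` describing which mask was empty.
#' @export
patientwise_surface <- function(truth, prediction, symmetric = FALSE) {
  check_same_geometry(truth, prediction)
  if (is_empty_mask(truth) || is_empty_mask(prediction)) {
    out <- na_surface_summary()
    attr(out, "flag") <- if (is_empty_mask(truth) && is_empty_mask(prediction)) {
      "both_masks_empty"
    } else if (is_empty_mask(truth)) "empty_truth" else "empty_prediction"
    return(out)
  }
  bt <- extract_boundary(truth)
  bp <- extract_boundary(prediction)
  d <- boundary_distances(bp, bt)
  if (symmetric) d <- c(d, boundary_distances(bt, bp))
  summarize_distances(d)
}

#' Structure-wise surface-distance summaries
#'
#' HD95/ASD/MSD computed separately for each *detected* predicted structure
#' (coverage fraction above threshold against the truth mask), with distances
#' running from that structure's boundary to the whole ground-truth boundary.
#' Undetected (false-positive) structures are excluded entirely, so these
#' summaries reflect boundary quality of the structures the prediction
#' actually found, uncontaminated by detection errors.
#'
#' @param truth A [binary_mask()] (nonempty) — the ground truth.
#' @param prediction A `structure_set` of the predicted mask on the same grid.
#' @param matches Optional `match_table` of `prediction` against `truth`
#'   (from [match_structures()]); computed at `threshold` if omitted.
#' @param threshold Coverage-fraction threshold used when `matches` is
#'   omitted; default 0.5.
#' @return A data frame with one row per detected structure: `label`,
#'   `cfrac`, `volume_mm3`, `n_distances`, `hd95_mm`, `asd_mm`, `msd_mm`.
#'   Zero rows when no structure is detected.
#' @export
structurewise_surface <- function(truth, prediction, matches = NULL,
                                  threshold = 0.5) {
  stopifnot(inherits(truth, "binary_mask"),
            inherits(prediction, "structure_set"))
  check_same_geometry(truth, prediction$mask)
  if (is_empty_mask(truth)) {
    stop("truth mask is empty; structure-wise distances are undefined")
  }
  if (is.null(matches)) {
    matches <- match_structures(prediction, truth, threshold)
  }
  bt <- extract_boundary(truth)
  detected <- matches[matches$detected, , drop = FALSE]
  rows <- lapply(seq_len(nrow(detected)), function(i) {
    lab <- detected$label[i]
    s <- prediction$structures[[lab]]
    sm <- structure_to_mask(s, prediction$mask)
    ss <- summarize_distances(boundary_distances(extract_boundary(sm), bt))
    data.frame(label = lab, cfrac = detected$cfrac[i],
               volume_mm3 = detected$volume_mm3[i],
               n_distances = ss$n_distances, hd95_mm = ss$hd95_mm,
               asd_mm = ss$asd_mm, msd_mm = ss$msd_mm)
  })
  if (length(rows) == 0) {
    return(data.frame(label = integer(0), cfrac = numeric(0),
                      volume_mm3 = numeric(0), n_distances = integer(0),
                      hd95_mm = numeric(0), asd_mm = numeric(0),
                      msd_mm = numeric(0)))
  }
  do.call(rbind, rows)
}
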