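#' Dice overlap between two masks
#'
#' The Dice score is the voxel-count overlap statistic
#' \deqn{Dice(X, \hat X) = |X \cap \hat X| / (\tfrac12 |X| + \tfrac12 |\hat X|),}
#' symmetric in its arguments and equal to 1 for identical nonempty masks.
#'
#' When both masks are empty the score is undefined as a ratio. By default the
#' pair is scored 1 (a prediction that correctly finds nothing) and a warning
#' is raised so cohort code can flag or exclude the case; set
#' `both_empty = NA` to report a missing value instead.
#'
#' @param truth,prediction [binary_mask()] objects on the same grid.
#' @param both_empty Value returned when both masks are empty (default `1`).
#' @return The Dice score in `[0, 1]` (or `both_empty` for two empty masks).
#' @export
dice <- function(truth, prediction, both_empty = 1) {
  check_same_geometry(truth, prediction)
  nt <- sum(truth$data)
  np <- sum(prediction$data)
  if (nt == 0 && np == 0) {
    warning("both masks are empty; Dice is undefined and reported as ",
            format(both_empty))
    return(both_empty)
  }
  inter <- sum(truth$data & prediction$data)
  inter / (0.5 * nt + 0.5 * np)
}

#' Coverage fraction of a structure by a reference mask
#'
#' The coverage fraction of structure \eqn{\hat X_k} against a reference mask
#' \eqn{X} is \eqn{|\hat X_k \cap X| / |\hat X_k|}: the fraction of the
#' structure's voxels that the reference also marks. The denominator is always
#' the queried structure, which makes the quantity directional — querying a
#' predicted structure against the whole truth mask answers "is this
#' prediction real?", while querying a truth structure against the whole
#' predicted mask answers "was this lesion found?".
#'
#' @param structure A structure entry from [label_components()], or a
#'   [binary_mask()] treated as a single structure.
#' @param reference_mask A [binary_mask()] on the same grid.
#' @return The coverage fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(structure, reference_mask) {
  stopifnot(inherits(reference_mask, "binary_mask"))
  if (inherits(structure, "binary_mask")) {
    check_same_geometry(structure, reference_mask)
    n <- sum(structure$data)
    if (n == 0) stop("structure is empty; coverage fraction is undefined")
    return(sum(structure$data & reference_mask$data) / n)
  }
  coords <- structure$coords
  if (is.null(coords) || nrow(coords) == 0) {
    stop("structure is empty; coverage fraction is undefined")
  }
  sum(reference_mask$data[coords]) / nrow(coords)
}

#' Match the structures of one mask against the whole of the other
#'
#' Computes the coverage fraction of every structure in `queried` against the
#' entire `reference` mask and classifies each structure as detected when its
#' coverage fraction exceeds the threshold. The comparison is strict
#' (`cfrac > threshold`) by default, so a structure sitting exactly at the
#' threshold is not detected; set `strict = FALSE` for `>=`.
#'
#' @param queried A `structure_set` from [label_components()].
#' @param reference A [binary_mask()] on the same grid.
#' @param threshold Detection threshold in `(0, 1)`; default 0.5.
#' @param strict Use strict `>` at the threshold (default `TRUE`).
#' @return A `match_table`: a data frame with one row per queried structure
#'   (`label`, `n_voxels`, `volume_mm3`, `cfrac`, `detected`), with the
#'   threshold and strictness stored as attributes.
#' @export
match_structures <- function(queried, reference, threshold = 0.5,
                             strict = TRUE) {
  stopifnot(inherits(queried, "structure_set"))
  check_same_geometry(queried$mask, reference)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1")
  }
  k <- length(queried$structures)
  cfrac <- vapply(queried$structures, coverage_fraction, numeric(1),
                  reference_mask = reference)
  tab <- data.frame(
    label = vapply(queried$structures, `[[`, integer(1), "label"),
    n_voxels = vapply(queried$structures, `[[`, numeric(1), "n_voxels"),
    volume_mm3 = vapply(queried$structures, `[[`, numeric(1), "volume_mm3"),
    cfrac = if (k) cfrac else numeric(0),
    detected = if (k) {
      if (strict) cfrac > threshold else cfrac >= threshold
    } else logical(0)
  )
  attr(tab, "threshold") <- threshold
  attr(tab, "strict") <- strict
  class(tab) <- c("match_table", class(tab))
  tab
}

#' Structure-level detection summary for a mask pair
#'
#' Matches structures in both directions and derives the structure-wise
#' detection metrics:
#' * `ppv_cnn = TP_CNN / (TP_CNN + FP)` — the fraction of predicted
#'   structures whose coverage by the whole truth mask exceeds the threshold;
#' * `sens_gt = TP_GT / (TP_GT + FN)` — the fraction of truth structures
#'   whose coverage by the whole predicted mask exceeds the threshold;
#' * `volume_true_mm3` / `volume_false_mm3` — the mean volume of detected /
#'   undetected predicted structures.
#'
#' True negative structures cannot be defined, so each ratio is reported as
#' `NA` (never coerced to 0 or 1) when its denominator is zero: PPV is
#' undefined with no predicted structures, sensitivity with no truth
#' structures, and a mean volume with no qualifying structures.
#'
#' @param truth,prediction `structure_set` objects from [label_components()]
#'   on the same grid.
#' @param threshold Coverage-fraction detection threshold; default 0.5.
#' @param strict Use strict `>` at the threshold (default `TRUE`).
#' @return A `detection_summary` list: `counts` (tp_cnn, fp, tp_gt, fn),
#'   `ppv_cnn`, `sens_gt`, `volume_true_mm3`, `volume_false_mm3`, and the two
#'   `match_table`s (`matches_prediction`, `matches_truth`).
#' @export
detection_summary <- function(truth, prediction, threshold = 0.5,
                              strict = TRUE) {
  stopifnot(inherits(truth, "structure_set"),
            inherits(prediction, "structure_set"))
  check_same_geometry(truth$mask, prediction$mask)
  mp <- match_structures(prediction, truth$mask, threshold, strict)
  mt <- match_structures(truth, prediction$mask, threshold, strict)
  tp_cnn <- sum(mp$detected)
  fp <- sum(!mp$detected)
  tp_gt <- sum(mt$detected)
  fn <- sum(!mt$detected)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  structure(list(
    counts = c(tp_cnn = tp_cnn, fp = fp, tp_gt = tp_gt, fn = fn),
    ppv_cnn = ratio(tp_cnn, tp_cnn + fp),
    sens_gt = ratio(tp_gt, tp_gt + fn),
    volume_true_mm3 = mean_or_na(mp$volume_mm3[mp$detected]),
    volume_false_mm3 = mean_or_na(mp$volume_mm3[!mp$detected]),
    threshold = threshold,
    matches_prediction = mp,
    matches_truth = mt
  ), class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("<detection_summary> threshold ", x$threshold, "\n", sep = "")
  cat("  TP_CNN ", x$counts[["tp_cnn"]], ", FP ", x$counts[["fp"]],
      ", TP_GT ", x$counts[["tp_gt"]], ", FN ", x$counts[["fn"]], "\n",
      sep = "")
  cat("  PPV_CNN ", format(x$ppv_cnn), ", Sens_GT ", format(x$sens_gt), "\n",
      sep = "")
  cat("  Volume_true ", format(x$volume_true_mm3), " mm^3, Volume_false ",
      format(x$volume_false_mm3), " mm^3\n", sep = "")
  invisible(x)
}
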