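#' Evaluate a prediction against ground truth
#'
#' One call computes the full metric panel for a mask pair:
#'
#' * patient-wise: Dice, and HD95/ASD/MSD of the directed whole-mask
#'   boundary-distance set (prediction to truth);
#' * structure-level detection: TP/FP/FN counts, `PPV_CNN`, `Sens_GT`, and
#'   mean true/false predicted-structure volumes (reported in cm^3);
#' * structure-wise: HD95/ASD/MSD per detected predicted structure, with
#'   distances to the whole truth boundary, excluding undetected structures.
#'
#' Degenerate inputs never produce sentinel numbers: undefined ratios and
#' distance summaries are `NA` and a human-readable flag is appended to
#' `flags`. Every number in the report is a pure function of the two masks
#' and the recorded configuration.
#'
#' @param truth,prediction [binary_mask()] objects on the same grid.
#' @param patient_id Identifier recorded in the report.
#' @param threshold Coverage-fraction detection threshold; default 0.5.
#' @param connectivity Component connectivity (6, 18 or 26); default 26.
#' @param strict Strict `>` at the threshold (default `TRUE`).
#' @param symmetric Pool both distance directions in the patient-wise
#'   summary; default `FALSE` (directed, prediction to truth).
#' @return An `evaluation_report` list: `patient_id`, `config`,
#'   `patientwise`, `detection`, `structurewise` (data frame), `flags`.
#' @examples
#' sp <- phantom_spec(c(24, 24, 24), c(1, 1, 1),
#'                    centers = rbind(c(8, 8, 8), c(17, 17, 17)),
#'                    radii = rbind(c(5, 5, 5), c(3, 3, 3)))
#' truth <- render_phantom(sp)
#' evaluate_pair(truth, truth, patient_id = "demo")
#' @export
evaluate_pair <- function(truth, prediction, patient_id = "patient",
                          threshold = 0.5, connectivity = 26, strict = TRUE,
                          symmetric = FALSE) {
  check_same_geometry(truth, prediction)
  flags <- character(0)
  empty_t <- is_empty_mask(truth)
  empty_p <- is_empty_mask(prediction)
  if (empty_t) flags <- c(flags, "empty_truth_mask")
  if (empty_p) flags <- c(flags, "empty_prediction_mask")

  dice_val <- withCallingHandlers(
    dice(truth, prediction),
    warning = function(w) {
      flags <<- c(flags, "both_empty_dice_defaulted")
      invokeRestart("muffleWarning")
    })

  pw <- patientwise_surface(truth, prediction, symmetric = symmetric)
  if (!is.null(attr(pw, "flag"))) {
    flags <- c(flags, paste0("patientwise_distances_undefined_",
                             attr(pw, "flag")))
  }

  ts <- label_components(truth, connectivity)
  ps <- label_components(prediction, connectivity)
  det <- detection_summary(ts, ps, threshold = threshold, strict = strict)
  if (is.na(det$ppv_cnn)) flags <- c(flags, "ppv_undefined_no_predicted_structures")
  if (is.na(det$sens_gt)) flags <- c(flags, "sens_undefined_no_truth_structures")

  if (!empty_t) {
    sw <- structurewise_surface(truth, ps, matches = det$matches_prediction)
  } else {
    sw <- structurewise_surface_empty()
    flags <- c(flags, "structurewise_undefined_empty_truth")
  }
  if (nrow(sw) == 0 && !empty_t) flags <- c(flags, "no_detected_structures")
  sw$volume_cm3 <- sw$volume_mm3 / 1000
  sw <- sw[, c("label", "cfrac", "volume_cm3", "n_distances",
               "hd95_mm", "asd_mm", "msd_mm")]

  structure(list(
    patient_id = patient_id,
    config = list(threshold = threshold, connectivity = connectivity,
                  strict = strict, symmetric = symmetric,
                  percentile_method = "linear_interpolation_type7"),
    patientwise = list(dice = dice_val, hd95_mm = pw$hd95_mm,
                       asd_mm = pw$asd_mm, msd_mm = pw$msd_mm),
    detection = list(
      tp_cnn = unname(det$counts[["tp_cnn"]]), fp = unname(det$counts[["fp"]]),
      tp_gt = unname(det$counts[["tp_gt"]]), fn = unname(det$counts[["fn"]]),
      ppv_cnn = det$ppv_cnn, sens_gt = det$sens_gt,
      volume_true_cm3 = det$volume_true_mm3 / 1000,
      volume_false_cm3 = det$volume_false_mm3 / 1000),
    structurewise = sw,
    flags = flags
  ), class = "evaluation_report")
}

structurewise_surface_empty <- function() {
  data.frame(label = integer(0), cfrac = numeric(0), volume_mm3 = numeric(0),
             n_distances = integer(0), hd95_mm = numeric(0),
             asd_mm = numeric(0), msd_mm = numeric(0))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> patient ", x$patient_id, "\n", sep = "")
  pw <- x$patientwise
  cat(sprintf("  patient-wise : Dice %.3f | HD95 %s mm | ASD %s mm | MSD %s mm\n",
              pw$dice, format(pw$hd95_mm, digits = 4),
              format(pw$asd_mm, digits = 4), format(pw$msd_mm, digits = 4)))
  d <- x$detection
  cat(sprintf("  detection    : TP_CNN %d FP %d TP_GT %d FN %d | PPV_CNN %s | Sens_GT %s\n",
              d$tp_cnn, d$fp, d$tp_gt, d$fn,
              format(d$ppv_cnn, digits = 4), format(d$sens_gt, digits = 4)))
  cat(sprintf("  volumes      : true %s cm^3 | false %s cm^3\n",
              format(d$volume_true_cm3, digits = 4),
              format(d$volume_false_cm3, digits = 4)))
  cat("  structure-wise (", nrow(x$structurewise), " detected):\n", sep = "")
  if (nrow(x$structurewise)) {
    print(format(x$structurewise, digits = 4), row.names = FALSE)
  }
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Output is deterministic: fixed key order, fixed float precision, `NA`
#' written as `null`. `read_report()` restores an equivalent report object,
#' so write/read round-trips to identical values at the serialised precision.
#'
#' @param report An `evaluation_report` from [evaluate_pair()].
#' @param path File path for [write_report()] / [read_report()].
#' @return `report_json()` returns a JSON string; `write_report()` returns
#'   `path` invisibly; `read_report()` returns an `evaluation_report`.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- unclass(report)
  x$flags <- as.list(x$flags)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, na = "null",
                   dataframe = "columns", pretty = TRUE)
}

#' @rdname report_json
#' @export
write_report <- function(report, path) {
  writeLines(report_json(report), path)
  invisible(path)
}

#' @rdname report_json
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sw <- as.data.frame(x$structurewise)
  if (nrow(sw) == 0) {
    sw <- structurewise_surface_empty()
    sw$volume_cm3 <- numeric(0)
    sw <- sw[, c("label", "cfrac", "volume_cm3", "n_distances",
                 "hd95_mm", "asd_mm", "msd_mm")]
  }
  null_na <- function(v) if (is.null(v)) NA_real_ else v
  x$patientwise <- lapply(x$patientwise, null_na)
  x$detection <- lapply(x$detection, null_na)
  structure(list(patient_id = x$patient_id, config = x$config,
                 patientwise = x$patientwise, detection = x$detection,
                 structurewise = sw,
                 flags = as.character(unlist(x$flags))),
            class = "evaluation_report")
}

# One row of per-patient metric values in reporting units (percent for
# fractions, mm for distances, cm^3 for volumes). Structure-wise distance
# metrics are the per-patient mean over detected structures, NA when none.
report_metric_row <- function(r) {
  sw <- r$structurewise
  sw_mean <- function(col) if (nrow(sw)) mean(sw[[col]]) else NA_real_
  data.frame(
    patient_id = r$patient_id,
    dice_pct = 100 * r$patientwise$dice,
    pw_asd_mm = r$patientwise$asd_mm,
    pw_msd_mm = r$patientwise$msd_mm,
    pw_hd95_mm = r$patientwise$hd95_mm,
    sens_gt_pct = 100 * r$detection$sens_gt,
    ppv_cnn_pct = 100 * r$detection$ppv_cnn,
    sw_asd_mm = sw_mean("asd_mm"),
    sw_msd_mm = sw_mean("msd_mm"),
    sw_hd95_mm = sw_mean("hd95_mm"),
    volume_true_cm3 = r$detection$volume_true_cm3,
    volume_false_cm3 = r$detection$volume_false_cm3,
    n_detected = nrow(sw)
  )
}

#' Summarise a cohort of evaluation reports
#'
#' Aggregates per-patient metrics as mean and sample standard deviation in
#' the conventional reporting units (percent for Dice/Sens/PPV, mm for
#' distances, cm^3 for volumes). Structure-wise metrics are pooled
#' per-patient first (mean over that patient's detected structures) and then
#' across patients, so patients with many structures do not dominate.
#' Undefined per-patient values (for example PPV with no predicted
#' structures, or structure-wise distances with no detected structures) are
#' excluded from the mean and counted in `n_excluded`.
#'
#' @param reports A list of `evaluation_report` objects.
#' @return A `cohort_summary`: `table` (data frame with `metric`, `mean`,
#'   `sd`, `n`, `n_excluded`), `per_patient` (the per-patient metric rows),
#'   and `n_zero_detected` (patients with no detected predicted structure).
#' @export
summarize_cohort <- function(reports) {
  if (length(reports) == 0) stop("need at least one evaluation report")
  stopifnot(all(vapply(reports, inherits, logical(1), "evaluation_report")))
  per <- do.call(rbind, lapply(reports, report_metric_row))
  metrics <- setdiff(names(per), c("patient_id", "n_detected"))
  tab <- do.call(rbind, lapply(metrics, function(m) {
    v <- per[[m]]
    ok <- !is.na(v)
    data.frame(metric = m,
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               sd = if (sum(ok) >= 2) stats::sd(v[ok]) else NA_real_,
               n = sum(ok), n_excluded = sum(!ok))
  }))
  structure(list(table = tab, per_patient = per,
                 n_zero_detected = sum(per$n_detected == 0)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", nrow(x$per_patient), " patient(s); ",
      x$n_zero_detected, " with zero detected structures\n", sep = "")
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Write a cohort summary (or its per-patient table) as CSV
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param path Output CSV path.
#' @param what `"summary"` (metric mean/sd table) or `"per_patient"`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(summary, path, what = c("summary", "per_patient")) {
  stopifnot(inherits(summary, "cohort_summary"))
  what <- match.arg(what)
  tab <- if (what == "summary") summary$table else summary$per_patient
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
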