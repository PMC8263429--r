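#' Built-in worked example: detection metrics on a three-structure prediction
#'
#' Constructs the canonical multi-structure teaching case on a single slice:
#' the ground truth holds two structures, the prediction three. Predicted
#' structure 1 closely matches truth structure 1 (high mutual coverage),
#' predicted structure 2 is a small blob inside the much larger truth
#' structure 2 (so the predicted structure is well covered, but the truth
#' structure is not), and predicted structure 3 overlaps nothing.
#'
#' At the default 0.5 coverage threshold this yields `TP_CNN = 2`, `FP = 1`
#' (so `PPV_CNN = 2/3`, 0.7 at one significant digit) and `TP_GT = 1`,
#' `FN = 1` (so `Sens_GT = 0.5`): detection looks good from the prediction's
#' perspective and mediocre from the truth's, which is exactly why both
#' directions are reported.
#'
#' @return A list with `truth` and `prediction` ([binary_mask()] objects,
#'   shape 40 x 32 x 1, 1 mm spacing).
#' @examples
#' ex <- worked_example_pair()
#' ts <- label_components(ex$truth)
#' ps <- label_components(ex$prediction)
#' detection_summary(ts, ps)
#' @export
worked_example_pair <- function() {
  d <- c(40L, 32L, 1L)
  truth <- array(FALSE, dim = d)
  pred <- array(FALSE, dim = d)
  # truth structure 1 and its slightly shifted prediction (90/100 overlap)
  truth[2:11, 2:11, 1] <- TRUE
  pred[2:11, 3:12, 1] <- TRUE
  # truth structure 2: large; predicted structure 2: small blob inside it
  truth[20:34, 2:16, 1] <- TRUE
  pred[24:27, 6:9, 1] <- TRUE
  # predicted structure 3: overlaps nothing
  pred[2:5, 24:27, 1] <- TRUE
  list(truth = binary_mask(truth, c(1, 1, 1)),
       prediction = binary_mask(pred, c(1, 1, 1)))
}
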