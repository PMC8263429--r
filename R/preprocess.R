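#' Hounsfield-unit soft-tissue window
#'
#' Clips CT intensities to the window `[center - width/2, center + width/2]`
#' and rescales the clipped values linearly to `[0, 1]`. The defaults (centre
#' 70 HU, width 200 HU, i.e. the range \[-30, 170\] HU) select the narrow
#' soft-tissue range in which tumours and involved lymph nodes live; bone and
#' air saturate at 1 and 0 respectively. The transform is monotone
#' non-decreasing and maps the window centre to 0.5.
#'
#' @param volume A numeric array (or vector) of CT values in HU.
#' @param center Window centre in HU; default 70.
#' @param width Window width in HU; must be positive. Default 200.
#' @return An object of the same shape with values in `[0, 1]`.
#' @examples
#' hu_window(c(-1000, -30, 70, 170, 1000))
#' @export
hu_window <- function(volume, center = 70, width = 200) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) ||
      width <= 0) {
    stop("`width` must be a single positive number (HU)")
  }
  if (!is.numeric(center) || length(center) != 1 || !is.finite(center)) {
    stop("`center` must be a single finite number (HU)")
  }
  lo <- center - width / 2
  hi <- center + width / 2
  (pmin(pmax(volume, lo), hi) - lo) / width
}
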