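#' Tidy an ROI detection evaluation
#'
#' @param x A `roi_evaluation` from [evaluate_detection()].
#' @param ... Unused.
#' @return A tibble with one row per accuracy measure (`sensitivity`,
#'   `specificity`, `ppv`, `npv`): `estimate`, `conf.low`, `conf.high`,
#'   `successes`, `trials`, `undefined`.
#' @export
tidy.roi_evaluation <- function(x, ...) {
  x$rates
}

#' Glance at an ROI detection evaluation
#'
#' @param x A `roi_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with confusion counts, point estimates and the
#'   correlation threshold.
#' @export
glance.roi_evaluation <- function(x, ...) {
  est <- setNames(x$rates$estimate, x$rates$measure)
  tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
         sensitivity = est[["sensitivity"]], specificity = est[["specificity"]],
         ppv = est[["ppv"]], npv = est[["npv"]],
         threshold_mm = x$threshold_mm, conf.level = x$level)
}

#' Tidy an annotation
#'
#' @param x An `egm_annotation` from [annotate_recording()].
#' @param ... Unused.
#' @return The quality-gated event tibble.
#' @export
tidy.egm_annotation <- function(x, ...) {
  x$events
}

#' Glance at an annotation
#'
#' @param x An `egm_annotation`.
#' @param ... Unused.
#' @return One-row tibble: channel and event totals.
#' @export
glance.egm_annotation <- function(x, ...) {
  tibble(n_channels = nrow(x$channels), n_passed = sum(x$channels$passed),
         n_events = nrow(x$events),
         median_snr = median(x$channels$snr[x$channels$passed]))
}
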