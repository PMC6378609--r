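#' Plot stacked unipolar electrograms
#'
#' @param object A `unipolar_recording`.
#' @param electrodes Electrode ids to show (default: first six channels).
#' @param t_range Optional time window `c(from_ms, to_ms)`.
#' @param ... Unused.
#' @return A ggplot object: voltage traces stacked per electrode.
#' @export
autoplot.unipolar_recording <- function(object, electrodes = NULL,
                                        t_range = NULL, ...) {
  if (is.null(electrodes)) electrodes <- head(colnames(object$traces), 6)
  df <- egm_tidy(object, electrodes)
  if (!is.null(t_range)) {
    df <- dplyr::filter(df, .data$time_ms >= t_range[1],
                        .data$time_ms <= t_range[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$voltage_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$electrode_id)) +
    ggplot2::labs(x = "time (ms)", y = "voltage (mV)",
                  title = object$meta$recording_id) +
    ggplot2::theme_minimal()
}

# unrolled (azimuth vs elevation) coordinates about the array centroid
unroll_positions <- function(pos) {
  ctr <- colMeans(pos)
  rel <- sweep(pos, 2, ctr)
  tibble(azimuth_deg = atan2(rel[, 2], rel[, 1]) * 180 / pi,
         elevation_deg = atan2(rel[, 3], sqrt(rel[, 1]^2 + rel[, 2]^2)) * 180 / pi)
}

#' Plot detected ROI sites on the unrolled array
#'
#' Electrode layout shown in azimuth/elevation about the array centroid,
#' with detected ROI sites sized by their occurrence count.
#'
#' @param object A `roi_sites` tibble from [detect_roi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roi_sites <- function(object, ...) {
  array <- attr(object, "array")
  pos <- electrode_positions(array)
  base <- dplyr::mutate(unroll_positions(pos),
                        electrode_id = rownames(pos))
  p <- ggplot2::ggplot(base, ggplot2::aes(.data$azimuth_deg,
                                          .data$elevation_deg)) +
    ggplot2::geom_point(shape = 1, colour = "grey60")
  if (nrow(object) > 0) {
    hits <- dplyr::left_join(as_tibble(object)[, c("electrode_id", "occurrences")],
                             base, by = "electrode_id")
    p <- p + ggplot2::geom_point(
      data = hits,
      ggplot2::aes(size = .data$occurrences), colour = "red3")
  }
  p + ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                    size = "occurrences", title = "ROI sites") +
    ggplot2::theme_minimal()
}

#' Plot detection accuracy with confidence intervals
#'
#' @param object A `roi_evaluation` from [evaluate_detection()].
#' @param ... Unused.
#' @return A ggplot object: point estimates with exact confidence intervals.
#' @export
autoplot.roi_evaluation <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !.data$undefined)
  ggplot2::ggplot(df, ggplot2::aes(.data$measure, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%d%%", round(100 * v)),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "rate (95% CI)") +
    ggplot2::theme_minimal()
}
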