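#' Filter specification for unipolar signals
#'
#' The conditioning chain applied to every channel: a band-pass (default
#' 2-240 Hz, fourth-order Butterworth) plus a mains notch (default 60 Hz,
#' quality 30; set `notch = NULL` for none, or 50 for 50 Hz regions). Both
#' stages are applied forward-backward (zero phase) so activation times are
#' not biased by group delay.
#'
#' @param band_low,band_high Band edges in Hz.
#' @param notch Notch center frequency in Hz, or `NULL` to disable.
#' @param notch_q Notch quality factor (center / -3 dB bandwidth).
#' @param order Band-pass filter order (even).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 2, band_high = 240, notch = 60,
                        notch_q = 30, order = 4) {
  if (!(band_low > 0 && band_low < band_high)) {
    abort("need 0 < band_low < band_high", class = "focalroi_error_filter")
  }
  if (order < 2 || order %% 2 != 0) {
    abort("order must be an even integer >= 2", class = "focalroi_error_filter")
  }
  if (!is.null(notch) && (notch <= band_low || notch >= band_high)) {
    abort("notch must lie inside the pass band (or be NULL)",
          class = "focalroi_error_filter")
  }
  structure(list(band_low = band_low, band_high = band_high, notch = notch,
                 notch_q = notch_q, order = order),
            class = "filter_spec")
}

# zero-phase filtering of one channel
filter_trace <- function(x, spec, sampling_rate) {
  nyq <- sampling_rate / 2
  bp <- signal::butter(spec$order / 2,
                       c(spec$band_low, spec$band_high) / nyq, type = "pass")
  y <- signal::filtfilt(bp, x)
  if (!is.null(spec$notch)) {
    bw <- spec$notch / spec$notch_q
    ns <- signal::butter(1, c(spec$notch - bw / 2, spec$notch + bw / 2) / nyq,
                         type = "stop")
    y <- signal::filtfilt(ns, y)
  }
  y
}

#' Filter a recording
#'
#' Applies the zero-phase band-pass/notch chain of a [filter_spec()] to all
#' channels of a recording.
#'
#' @param recording A `unipolar_recording`.
#' @param spec A `filter_spec`.
#' @return A filtered `unipolar_recording` (same shape and metadata).
#' @export
filter_unipolar <- function(recording, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) spec <- do.call(filter_spec, spec)
  nyq <- recording$sampling_rate / 2
  if (spec$band_high >= nyq) {
    abort(sprintf(
      "band_high (%g Hz) must be below the Nyquist frequency (%g Hz); lower band_high or resample",
      spec$band_high, nyq), class = "focalroi_error_filter")
  }
  out <- recording
  out$traces <- apply(recording$traces, 2, filter_trace, spec = spec,
                      sampling_rate = recording$sampling_rate)
  colnames(out$traces) <- colnames(recording$traces)
  out
}
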