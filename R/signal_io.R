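#' Multichannel unipolar recording
#'
#' Container for a multichannel unipolar electrogram recording: a samples x
#' electrodes voltage matrix (mV), the sampling rate, the electrode array
#' the channels map onto, and recording metadata. The nominal recording
#' length is 30 s; shorter recordings are accepted with a warning.
#'
#' @param traces Numeric matrix, rows = samples, columns = electrodes;
#'   column names must be electrode ids present in `array`.
#' @param sampling_rate Sampling rate in Hz (>= 500).
#' @param array An `electrode_array`.
#' @param stage Recording stage: `"pre_pvi"`, `"post_pvi"` or `"n/a"`.
#' @param recording_id,patient_id Identifiers (patient optional).
#' @return An object of class `unipolar_recording`.
#' @export
unipolar_recording <- function(traces, sampling_rate, array,
                               stage = c("n/a", "pre_pvi", "post_pvi"),
                               recording_id = "rec", patient_id = NULL) {
  stage <- match.arg(stage)
  traces <- as.matrix(traces)
  if (!is.numeric(traces) || anyNA(traces) || !all(is.finite(traces))) {
    abort("traces must be a finite numeric matrix",
          class = "focalroi_error_signal")
  }
  if (!is.numeric(sampling_rate) || sampling_rate < 500) {
    abort("sampling_rate must be >= 500 Hz", class = "focalroi_error_signal")
  }
  ids <- colnames(traces)
  if (is.null(ids)) {
    abort("traces must have electrode ids as column names",
          class = "focalroi_error_signal")
  }
  unknown <- setdiff(ids, array$electrodes$electrode_id)
  if (length(unknown)) {
    abort(paste("unknown electrode:", paste(unknown, collapse = ", ")),
          class = "focalroi_error_unknown_electrode")
  }
  duration <- nrow(traces) / sampling_rate
  if (duration < 30 - 1e-9) {
    warn(sprintf("recording is %.1f s, shorter than the nominal 30 s", duration),
         class = "focalroi_warn_short_recording")
  }
  structure(list(traces = traces, sampling_rate = sampling_rate,
                 duration = duration, array = array,
                 meta = list(recording_id = recording_id, stage = stage,
                             patient_id = patient_id)),
            class = "unipolar_recording")
}

#' @export
print.unipolar_recording <- function(x, ...) {
  cat(sprintf("<unipolar_recording '%s': %d ch x %.1f s @ %g Hz, stage %s>\n",
              x$meta$recording_id, ncol(x$traces), x$duration,
              x$sampling_rate, x$meta$stage))
  invisible(x)
}

#' Recording as a long tibble
#'
#' @param recording A `unipolar_recording`.
#' @param electrodes Optional electrode ids to keep.
#' @return Tibble with `electrode_id`, `time_ms`, `voltage_mv`.
#' @export
egm_tidy <- function(recording, electrodes = NULL) {
  ids <- colnames(recording$traces)
  if (!is.null(electrodes)) ids <- intersect(ids, electrodes)
  t_ms <- (seq_len(nrow(recording$traces)) - 1) / recording$sampling_rate * 1000
  purrr::map_dfr(ids, function(id) {
    tibble(electrode_id = id, time_ms = t_ms,
           voltage_mv = recording$traces[, id])
  })
}

fmt_num <- function(x) sprintf("%.12g", x)

#' Save a recording bundle
#'
#' Writes a metadata JSON (`<prefix>.meta.json`) and a signal CSV
#' (`<prefix>.signals.csv`, rows = samples, columns = electrode ids with a
#' header row). Output is byte-stable: fixed key order and a fixed float
#' format, so identical recordings produce identical files.
#'
#' @param recording A `unipolar_recording`.
#' @param prefix File path prefix (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
save_bundle <- function(recording, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) {
    abort(paste("directory does not exist:", dir),
          class = "focalroi_error_io")
  }
  meta <- list(
    recording_id = recording$meta$recording_id,
    stage = recording$meta$stage,
    patient_id = recording$meta$patient_id,
    sampling_rate = recording$sampling_rate,
    duration = recording$duration,
    n_samples = nrow(recording$traces),
    electrode_ids = colnames(recording$traces),
    array = array_to_list(recording$array)
  )
  meta_path <- paste0(prefix, ".meta.json")
  csv_path <- paste0(prefix, ".signals.csv")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"), meta_path)
  con <- file(csv_path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(recording$traces), collapse = ","), con)
  body <- apply(recording$traces, 1, function(row)
    paste(fmt_num(row), collapse = ","))
  writeLines(body, con)
  invisible(c(meta_path, csv_path))
}

#' Load a recording bundle
#'
#' Reads and cross-validates the metadata/CSV pair written by
#' [save_bundle()]. Mismatches raise classed errors naming the offending
#' field (`focalroi_error_header_mismatch`, `focalroi_error_unknown_electrode`,
#' `focalroi_error_non_numeric`, `focalroi_error_missing_geometry`).
#'
#' @param prefix File path prefix used at save time.
#' @return A `unipolar_recording`.
#' @export
load_bundle <- function(prefix) {
  meta_path <- paste0(prefix, ".meta.json")
  csv_path <- paste0(prefix, ".signals.csv")
  if (!file.exists(meta_path) || !file.exists(csv_path)) {
    abort("bundle files not found", class = "focalroi_error_io")
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = FALSE)
  if (is.null(meta$array)) {
    abort("metadata is missing the electrode array geometry",
          class = "focalroi_error_missing_geometry")
  }
  arr <- array_from_list(meta$array)
  dat <- read.csv(csv_path, check.names = FALSE)
  ids_meta <- unlist(meta$electrode_ids)
  if (!identical(names(dat), ids_meta)) {
    abort("CSV header does not match metadata electrode list",
          class = "focalroi_error_header_mismatch")
  }
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    abort("non-numeric cells in signal CSV",
          class = "focalroi_error_non_numeric")
  }
  if (nrow(dat) != meta$n_samples) {
    abort("sample count does not match metadata",
          class = "focalroi_error_header_mismatch")
  }
  traces <- as.matrix(dat)
  colnames(traces) <- ids_meta
  unipolar_recording(traces, meta$sampling_rate, arr,
                     stage = meta$stage,
                     recording_id = meta$recording_id,
                     patient_id = meta$patient_id)
}
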