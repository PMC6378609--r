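#' Run configuration
#'
#' A single nested list holding every tunable parameter of the pipeline
#' (filter, annotator, ROI detector, metrics, simulator, seed), suitable for
#' YAML/JSON round-tripping by the command-line interface. Unknown keys are
#' rejected so misspelled options cannot silently fall back to defaults.
#'
#' @param overrides Nested named list of overrides.
#' @return The effective configuration (named list).
#' @export
run_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1,
    filter = unclass(filter_spec()),
    annotate = annotate_params(),
    roi = roi_params(),
    metrics = list(threshold_mm = 10, slowing_ms = 30, lvz_mv = 0.5,
                   n_cycles = 30, ci = "exact", level = 0.95),
    simulate = default_sim_params()
  )
  check_keys <- function(ov, def, path = "") {
    unknown <- setdiff(names(ov), names(def))
    if (length(unknown)) {
      abort(sprintf("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
                    paste0(path, unknown, collapse = ", ")),
            class = "focalroi_error_config")
    }
    for (k in names(ov)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(ov[[k]])) {
        check_keys(ov[[k]], def[[k]], paste0(path, k, "."))
      }
    }
  }
  check_keys(overrides, defaults)
  utils::modifyList(defaults, overrides)
}
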