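#' Driver characterization metrics
#'
#' Summarizes how a putative driver site behaves across a set of maps:
#' \itemize{
#'   \item consistency - proportion of maps showing a correlating ROI site;
#'   \item temporal stability - mean consecutive repetitions per counted
#'     occurrence (over all counted runs at correlating sites);
#'   \item recurrence rate - mean number of counted occurrences per
#'     30-second recording.
#' }
#' Maps flagged as not covering the driver's location are excluded from the
#' consistency denominator only.
#'
#' @param sites Tibble of ROI sites across maps with columns `recording_id`,
#'   `x`, `y`, `z`, `occurrences` and `runs` (list column); e.g. row-bound
#'   [detect_roi()] outputs.
#' @param position Driver position, 3-vector (mm).
#' @param map_ids Character vector of all map/recording ids considered
#'   (including maps with no detection).
#' @param uncovered Ids of maps whose coverage missed the driver site.
#' @param threshold_mm Correlation distance (mm), strict.
#' @return One-row tibble: `consistency`, `temporal_stability`,
#'   `recurrence_rate`, `n_maps`, `n_maps_present`.
#' @export
driver_metrics <- function(sites, position, map_ids,
                           uncovered = character(), threshold_mm = 10) {
  if (length(map_ids) == 0) {
    abort("driver_metrics requires at least one map",
          class = "focalroi_error_metrics")
  }
  sites <- as_tibble(sites)
  if (nrow(sites) > 0) {
    d <- sqrt((sites$x - position[1])^2 + (sites$y - position[2])^2 +
                (sites$z - position[3])^2)
    hits <- sites[d < threshold_mm, ]
  } else {
    hits <- sites
  }
  present_maps <- unique(hits$recording_id)
  denom_maps <- setdiff(map_ids, uncovered)
  run_lengths <- unlist(hits$runs)
  occ_per_map <- vapply(map_ids, function(m)
    sum(hits$occurrences[hits$recording_id == m]), numeric(1))
  tibble(
    consistency = length(intersect(present_maps, denom_maps)) /
      max(1, length(denom_maps)),
    temporal_stability = if (length(run_lengths)) mean(run_lengths) else NA_real_,
    recurrence_rate = mean(occ_per_map),
    n_maps = length(map_ids),
    n_maps_present = length(present_maps)
  )
}

#' Mean cycle length from annotated activations
#'
#' Mean inter-activation interval over the first `n_cycles` intervals,
#' the conventional way fibrillation cycle length is read from a reference
#' channel.
#'
#' @param x Either a numeric vector of annotated activation times (ms), or
#'   a raw voltage trace if `sampling_rate` is given (it is then annotated
#'   with [detect_activations()] first).
#' @param sampling_rate Sampling rate (Hz) when `x` is a trace.
#' @param n_cycles Number of intervals to average (default 30).
#' @param params Annotator parameters when `x` is a trace.
#' @return Cycle length in ms.
#' @export
cycle_length <- function(x, sampling_rate = NULL, n_cycles = 30,
                         params = annotate_params()) {
  lats <- if (is.null(sampling_rate)) sort(as.numeric(x))
          else detect_activations(x, sampling_rate, params)$lat_ms
  if (length(lats) < n_cycles + 1) {
    abort(sprintf("need at least %d activations, got %d",
                  n_cycles + 1, length(lats)),
          class = "focalroi_error_metrics")
  }
  mean(diff(lats)[seq_len(n_cycles)])
}

#' Classify the response to ablation at a driver site
#'
#' `termination` if fibrillation terminated; otherwise `cl_slowing` when the
#' post-ablation cycle length exceeds the pre-ablation one by at least
#' 30 ms; otherwise `none`.
#'
#' @param pre_cl,post_cl Cycle lengths (ms).
#' @param terminated Logical.
#' @param slowing_ms Slowing threshold (ms, default 30).
#' @return Character vector of labels.
#' @export
ablation_response <- function(pre_cl, post_cl, terminated = FALSE,
                              slowing_ms = 30) {
  n <- max(length(pre_cl), length(post_cl), length(terminated))
  pre_cl <- rep_len(pre_cl, n); post_cl <- rep_len(post_cl, n)
  terminated <- rep_len(terminated, n)
  ifelse(terminated, "termination",
         ifelse(post_cl - pre_cl >= slowing_ms, "cl_slowing", "none"))
}

#' Low-voltage-zone classification
#'
#' A site is a low-voltage zone when its bipolar voltage is strictly below
#' 0.5 mV.
#'
#' @param bipolar_voltage_mv Non-negative voltage(s), mV.
#' @param threshold_mv Threshold (mV), strict.
#' @return Logical vector.
#' @export
lvz_classify <- function(bipolar_voltage_mv, threshold_mv = 0.5) {
  if (any(bipolar_voltage_mv < 0, na.rm = TRUE)) {
    abort("bipolar voltage must be non-negative",
          class = "focalroi_error_metrics")
  }
  bipolar_voltage_mv < threshold_mv
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles; the lower bound is 0 when
#' there are no successes and the upper bound 1 when all trials succeed.
#'
#' @param successes,trials Non-negative integer counts, `successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @export
binomial_ci_exact <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    abort("need integer 0 <= successes <= trials, trials >= 1",
          class = "focalroi_error_metrics")
  }
  alpha <- 1 - level
  low <- if (successes == 0) 0 else qbeta(alpha / 2, successes,
                                          trials - successes + 1)
  high <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1,
                                                trials - successes)
  c(low = low, high = high)
}

#' Wilson score interval (alternative to the exact interval)
#'
#' @inheritParams binomial_ci_exact
#' @return Numeric vector `c(low, high)`.
#' @export
binomial_ci_wilson <- function(successes, trials, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  den <- 1 + z^2 / trials
  ctr <- (p + z^2 / (2 * trials)) / den
  hw <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' the observed table's, with margins fixed.
#'
#' @param a,b,c,d Cell counts, table rows `(a, b)` and `(c, d)`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 1) {
    abort("cells must be non-negative integers with a positive total",
          class = "focalroi_error_metrics")
  }
  stats::fisher.test(matrix(counts, 2, byrow = TRUE))$p.value
}

#' Evaluate ROI detection against reference driver sites
#'
#' Site-level confusion counts under the strict 1 cm correlation rule:
#' a reference driver is a true positive when at least one detected ROI site
#' lies strictly within `threshold_mm`; detected sites correlating with no
#' reference are false positives; explicit control sites (driver-free
#' locations, each at least `2 * threshold_mm` from every reference) with no
#' correlating ROI site are true negatives. Rates carry exact two-sided
#' confidence intervals.
#'
#' @param roi_sites Tibble with `x`, `y`, `z` of detected sites.
#' @param reference_drivers Tibble with `x`, `y`, `z` of reference driver
#'   sites; may be empty (sensitivity is then undefined and flagged).
#' @param control_sites Tibble with `x`, `y`, `z` of driver-free control
#'   sites.
#' @param threshold_mm Correlation distance (mm), strict.
#' @param level Confidence level for the exact intervals.
#' @param ci One of `"exact"`, `"wilson"`.
#' @return An object of class `roi_evaluation`: confusion counts, a rate
#'   table with confidence intervals, and the settings used. Use
#'   [tidy()] / [glance()] to extract tibbles.
#' @export
evaluate_detection <- function(roi_sites, reference_drivers, control_sites,
                               threshold_mm = 10, level = 0.95,
                               ci = c("exact", "wilson")) {
  ci <- match.arg(ci)
  pos <- function(df) as.matrix(as_tibble(df)[, c("x", "y", "z")])
  roi <- pos(roi_sites); ref <- pos(reference_drivers); ctl <- pos(control_sites)
  if (nrow(ref) > 0 && nrow(ctl) > 0) {
    dmin <- min(cross_dist(ctl, ref))
    if (dmin < 2 * threshold_mm) {
      abort(sprintf(
        "control sites must be at least %g mm from every reference (closest: %.1f mm)",
        2 * threshold_mm, dmin), class = "focalroi_error_metrics")
    }
  }
  ref_hit <- if (nrow(ref) == 0) logical(0)
             else if (nrow(roi) == 0) rep(FALSE, nrow(ref))
             else apply(cross_dist(ref, roi), 1, min) < threshold_mm
  roi_hit <- if (nrow(roi) == 0) logical(0)
             else if (nrow(ref) == 0) rep(FALSE, nrow(roi))
             else apply(cross_dist(roi, ref), 1, min) < threshold_mm
  ctl_hit <- if (nrow(ctl) == 0) logical(0)
             else if (nrow(roi) == 0) rep(FALSE, nrow(ctl))
             else apply(cross_dist(ctl, roi), 1, min) < threshold_mm
  tp <- sum(ref_hit); fn <- sum(!ref_hit)
  fp <- sum(!roi_hit); tn <- sum(!ctl_hit)
  ci_fun <- if (ci == "exact") binomial_ci_exact else binomial_ci_wilson
  rate_row <- function(name, s, n) {
    if (n == 0) {
      return(tibble(measure = name, estimate = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, successes = s, trials = n,
                    undefined = TRUE))
    }
    b <- ci_fun(s, n, level)
    tibble(measure = name, estimate = s / n, conf.low = b[["low"]],
           conf.high = b[["high"]], successes = s, trials = n,
           undefined = FALSE)
  }
  rates <- dplyr::bind_rows(
    rate_row("sensitivity", tp, tp + fn),
    rate_row("specificity", tn, tn + fp),
    rate_row("ppv", tp, tp + fp),
    rate_row("npv", tn, tn + fn)
  )
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, rates = rates,
                 threshold_mm = threshold_mm, level = level, ci = ci),
            class = "roi_evaluation")
}

#' @export
print.roi_evaluation <- function(x, ...) {
  cat(sprintf("<roi_evaluation: tp %d, fn %d, fp %d, tn %d (threshold %g mm)>\n",
              x$tp, x$fn, x$fp, x$tn, x$threshold_mm))
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    if (r$undefined[i]) {
      cat(sprintf("  %-12s undefined (no trials)\n", r$measure[i]))
    } else {
      cat(sprintf("  %-12s %s\n", r$measure[i],
                  format_rate_pct(r$estimate[i], r$conf.low[i], r$conf.high[i])))
    }
  }
  invisible(x)
}

#' Format a rate as an integer percentage with its interval
#'
#' Half-up integer rounding, e.g. `"73 (54-88)"`.
#'
#' @param estimate,low,high Proportions in `[0, 1]`.
#' @return Character scalar.
#' @export
format_rate_pct <- function(estimate, low, high) {
  sprintf("%d (%d-%d)", round_half_up(100 * estimate),
          round_half_up(100 * low), round_half_up(100 * high))
}
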