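#' Default annotation parameters
#'
#' Parameters for the surrogate unipolar annotator and the channel quality
#' gate. The annotator marks local activation times (LAT) at local maxima of
#' the negative slope -dV/dt, the standard unipolar convention; the gate
#' ignores channels that do not carry enough usable atrial signal.
#'
#' @param blanking_ms Refractory spacing between accepted activations (ms).
#' @param min_slope Absolute floor on the negative slope magnitude at the
#'   LAT (mV/ms). The working threshold is adaptive,
#'   `max(min_slope, noise_k * sd_noise)` with `sd_noise` the channel's
#'   white-noise floor propagated through the slope kernel, so detection is
#'   invariant to amplitude rescaling.
#' @param noise_k Multiplier on the robust noise level of the slope signal.
#' @param window_ms Morphology window centered on the LAT (ms); the R-wave
#'   amplitude is the largest positive deflection in the half-window before
#'   the LAT, the S-wave amplitude the largest negative deflection in the
#'   full window.
#' @param slope_smooth_ms Gaussian smoothing scale for the slope estimate
#'   (ms); suppresses sample-to-sample noise without biasing timing.
#' @param qs_threshold Maximum R fraction `r/(r+s)` for a QS label.
#' @param qs_min_snr A QS label additionally requires the S amplitude to
#'   exceed this multiple of the channel's noise floor.
#' @param min_beats Minimum activation count per 30 s (scaled to duration).
#' @param min_snr Minimum signal-to-noise ratio (median event amplitude over
#'   robust noise level).
#' @param min_p2p_mv Minimum peak-to-peak trace amplitude (mV).
#' @param freq_band_hz Acceptable dominant-frequency band (Hz).
#' @return A named list of parameters.
#' @export
annotate_params <- function(blanking_ms = 60, min_slope = 0.01, noise_k = 5,
                            window_ms = 40, slope_smooth_ms = 3,
                            qs_threshold = 0.10, qs_min_snr = 5,
                            min_beats = 15,
                            min_snr = 3, min_p2p_mv = 0.05,
                            freq_band_hz = c(3, 12)) {
  list(blanking_ms = blanking_ms, min_slope = min_slope, noise_k = noise_k,
       window_ms = window_ms, slope_smooth_ms = slope_smooth_ms,
       qs_threshold = qs_threshold, qs_min_snr = qs_min_snr,
       min_beats = min_beats,
       min_snr = min_snr, min_p2p_mv = min_p2p_mv,
       freq_band_hz = freq_band_hz)
}

# Gaussian smoothing with unit-sum kernel (sigma in samples)
gauss_smooth <- function(x, sg) {
  sg <- max(sg, 0.5)
  half <- ceiling(3 * sg)
  k <- dnorm(seq(-half, half), sd = sg)
  k <- k / sum(k)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- 0
  structure(as.numeric(y), k2 = sqrt(sum(k^2)))
}

# smoothed derivative in mV/ms via a derivative-of-Gaussian kernel;
# attribute "k2" carries the kernel L2 norm for noise propagation
smoothed_slope <- function(x, sampling_rate, slope_smooth_ms) {
  sg <- max(1, slope_smooth_ms * sampling_rate / 1000)
  half <- ceiling(4 * sg)
  tt <- seq(-half, half)
  k <- -tt * exp(-tt^2 / (2 * sg^2))
  k <- k / sum(-k * tt)                     # unit response to a unit ramp
  d <- stats::filter(x, k, sides = 2)
  d[is.na(d)] <- 0
  structure(as.numeric(d) * sampling_rate / 1000, k2 = sqrt(sum(k^2)))
}

# robust white-noise standard deviation from successive differences
noise_sd_est <- function(x) {
  mad(diff(x)) / sqrt(2)
}

# noise level of a (possibly colored) signal from the low quantile of
# chunk-wise scales: chunks overlapping activation waves inflate the upper
# quantiles only
noise_sigma_chunks <- function(d, chunk = 64, prob = 0.2) {
  nc <- floor(length(d) / chunk)
  if (nc < 2) return(stats::sd(d))
  m <- matrix(d[seq_len(nc * chunk)], chunk)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu * mu
  sqrt(max(0, stats::quantile(v, prob, names = FALSE)))
}

#' Detect atrial activations on one unipolar channel
#'
#' Surrogate LAT annotator: activations are local maxima of the negative
#' slope exceeding `min_slope`, accepted greedily from steepest downward and
#' separated by at least `blanking_ms`. Per-event morphology amplitudes are
#' measured in a `window_ms` window about the LAT and the QS / non-QS label
#' assigned by [classify_morphology()].
#'
#' @param trace Numeric voltage vector (mV), ideally filtered.
#' @param sampling_rate Sampling rate (Hz).
#' @param params See [annotate_params()].
#' @return Tibble with one row per activation: `lat_ms`, `neg_slope`,
#'   `r_amp`, `s_amp`, `r_fraction`, `morphology`, `degenerate`.
#' @export
detect_activations <- function(trace, sampling_rate, params = annotate_params()) {
  empty <- tibble(lat_ms = numeric(), neg_slope = numeric(),
                  r_amp = numeric(), s_amp = numeric(),
                  r_fraction = numeric(), morphology = character(),
                  degenerate = logical())
  n <- length(trace)
  if (n < 3 || diff(range(trace)) == 0) return(empty)
  d <- smoothed_slope(trace, sampling_rate, params$slope_smooth_ms)
  # slope noise level estimated from quiet chunks of the slope signal
  # itself, so the threshold tracks colored noise without inflating with
  # signal occupancy
  sd_slope <- noise_sigma_chunks(d)
  thr <- max(params$min_slope, params$noise_k * sd_slope)
  cand <- which(d < -thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[d[cand] <= d[cand - 1] & d[cand] < d[cand + 1]]
  if (!length(cand)) return(empty)
  blank <- params$blanking_ms * sampling_rate / 1000
  cand <- cand[order(d[cand])]
  accepted <- integer()
  for (i in cand) {
    if (!length(accepted) || all(abs(accepted - i) >= blank)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  # amplitudes read off a lightly smoothed trace, debiased by the channel's
  # robust noise floor, so broadband noise does not masquerade as an initial
  # R wave
  sm <- gauss_smooth(trace, params$slope_smooth_ms * sampling_rate / 1000)
  noise_floor <- 2.5 * noise_sd_est(trace) * attr(sm, "k2")
  half <- round(params$window_ms / 2 * sampling_rate / 1000)
  r_amp <- s_amp <- numeric(length(accepted))
  for (k in seq_along(accepted)) {
    i <- accepted[k]
    pre <- sm[max(1, i - half):i]
    win <- sm[max(1, i - half):min(n, i + half)]
    # slow positive baseline (e.g. DC-block recovery of surrounding waves)
    # is not an R wave: measure the R deflection relative to it
    base <- max(0, pre[1])
    r_amp[k] <- max(0, max(pre) - base - noise_floor)
    s_amp[k] <- max(0, -min(win) - noise_floor)
  }
  out <- tibble(lat_ms = (accepted - 1) / sampling_rate * 1000,
                neg_slope = -d[accepted], r_amp = r_amp, s_amp = s_amp)
  out <- classify_morphology(out, qs_threshold = params$qs_threshold)
  # a QS call must stand clear of the channel's noise floor: noise-scale
  # negative deflections carry no morphology information
  s_floor <- params$qs_min_snr * noise_sd_est(trace) * attr(sm, "k2")
  out$morphology[out$morphology == "QS" & out$s_amp < s_floor] <- "non_QS"
  out
}

#' Classify unipolar event morphology
#'
#' A unipolar activation is labelled `QS` (entirely negative deflection, the
#' signature of a site activation spreads away from) when its R fraction
#' `r_amp / (r_amp + s_amp)` is at most `qs_threshold`; otherwise `non_QS`.
#' Events with no measurable deflection are flagged degenerate and labelled
#' `non_QS`.
#'
#' @param events Data frame with `r_amp` and `s_amp` columns (mV).
#' @param qs_threshold Maximum R fraction for a QS label (default 0.10).
#' @return The events tibble with `r_fraction`, `morphology` and
#'   `degenerate` columns.
#' @export
classify_morphology <- function(events, qs_threshold = 0.10) {
  events <- as_tibble(events)
  tot <- events$r_amp + events$s_amp
  degenerate <- tot <= 0
  r_fraction <- ifelse(degenerate, NA_real_, events$r_amp / tot)
  morphology <- ifelse(!degenerate & r_fraction <= qs_threshold, "QS", "non_QS")
  dplyr::mutate(events, r_fraction = r_fraction, morphology = morphology,
                degenerate = degenerate)
}

# dominant frequency (Hz) of the rectified, smoothed trace
dominant_frequency <- function(trace, sampling_rate, f_min = 2, f_max = 30) {
  n <- length(trace)
  env <- abs(trace)
  # ~25 ms moving-average envelope smoothing via cumulative sums
  w <- max(2, round(0.0125 * sampling_rate))
  cs <- cumsum(c(0, env))
  lo <- pmax(0, seq_len(n) - w)
  hi <- pmin(n, seq_len(n) + w)
  env <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  env <- env - mean(env)
  spec <- Mod(fft(as.numeric(env)))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * sampling_rate / n
  # slow amplitude modulation (e.g. the run-rate of an intermittent driver)
  # is not an activation rate: search above f_min only
  keep <- freq >= f_min & freq <= f_max
  if (!any(keep)) return(NA_real_)
  freq[keep][which.max(spec[keep])]
}

#' Quality-gate one channel
#'
#' Labels a channel as usable or ignored, mirroring the clinical behavior of
#' refusing to annotate low-quality electrodes. A channel passes when it has
#' enough beats, sufficient signal-to-noise ratio, sufficient peak-to-peak
#' amplitude, and a dominant frequency inside the atrial band. The gate
#' never raises: it returns a verdict with reasons.
#'
#' @param trace Numeric voltage vector (mV).
#' @param events Events from [detect_activations()].
#' @param sampling_rate Sampling rate (Hz).
#' @param params See [annotate_params()]; `min_beats` is interpreted per
#'   30 s and scaled to the trace duration.
#' @return One-row tibble: `passed`, `reasons` (list column), `beat_count`,
#'   `snr`, `p2p_mv`, `dominant_frequency`.
#' @export
quality_gate <- function(trace, events, sampling_rate,
                         params = annotate_params()) {
  duration_s <- length(trace) / sampling_rate
  need_beats <- ceiling(params$min_beats * duration_s / 30)
  beat_count <- nrow(events)
  p2p <- diff(range(trace))
  noise <- noise_sigma_chunks(trace)
  # per-event peak-to-peak on the raw trace: the gate judges the channel's
  # own signal content, independent of the morphology measurements
  half <- round(params$window_ms / 2 * sampling_rate / 1000)
  ev_p2p <- vapply(events$lat_ms, function(lat) {
    i <- round(lat * sampling_rate / 1000) + 1
    win <- trace[max(1, i - half):min(length(trace), i + half)]
    diff(range(win))
  }, numeric(1))
  snr <- if (beat_count == 0) 0
         else if (noise <= 0) Inf
         else median(ev_p2p) / noise
  df <- dominant_frequency(trace, sampling_rate)
  reasons <- character()
  if (beat_count < need_beats) reasons <- c(reasons, "too_few_beats")
  if (snr < params$min_snr) reasons <- c(reasons, "low_snr")
  if (p2p < params$min_p2p_mv) reasons <- c(reasons, "low_amplitude")
  if (is.na(df) || df < params$freq_band_hz[1] || df > params$freq_band_hz[2]) {
    reasons <- c(reasons, "off_band_frequency")
  }
  tibble(passed = length(reasons) == 0, reasons = list(reasons),
         beat_count = beat_count, snr = snr, p2p_mv = p2p,
         dominant_frequency = df)
}

#' Annotate all channels of a recording
#'
#' Runs [detect_activations()] and [quality_gate()] on every channel.
#' Channels that fail the gate are ignored: their events are dropped from
#' the event table, so they contribute no timings downstream.
#'
#' @param recording A (filtered) `unipolar_recording`.
#' @param params See [annotate_params()].
#' @return An object of class `egm_annotation`: list with `events` (tibble,
#'   quality-passed channels only, ordered by electrode and LAT) and
#'   `channels` (per-channel quality tibble), plus the parameters used.
#' @export
annotate_recording <- function(recording, params = annotate_params()) {
  ids <- colnames(recording$traces)
  per <- purrr::map(ids, function(id) {
    ev <- detect_activations(recording$traces[, id], recording$sampling_rate,
                             params)
    q <- quality_gate(recording$traces[, id], ev, recording$sampling_rate,
                      params)
    list(events = dplyr::mutate(ev, electrode_id = id, .before = 1),
         quality = dplyr::mutate(q, electrode_id = id, .before = 1))
  })
  channels <- dplyr::bind_rows(purrr::map(per, "quality"))
  passed_ids <- channels$electrode_id[channels$passed]
  events <- dplyr::bind_rows(purrr::map(per, "events"))
  events <- dplyr::filter(events, .data$electrode_id %in% passed_ids)
  structure(list(events = events, channels = channels, params = params,
                 sampling_rate = recording$sampling_rate,
                 duration = recording$duration),
            class = "egm_annotation")
}

#' @export
print.egm_annotation <- function(x, ...) {
  cat(sprintf("<egm_annotation: %d events on %d/%d channels>\n",
              nrow(x$events), sum(x$channels$passed), nrow(x$channels)))
  invisible(x)
}
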