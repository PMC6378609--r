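# shared test fixtures, all built in code

# short recordings are used throughout unit tests; silence the nominal-30 s
# warning they trigger
quiet_recording <- function(...) {
  suppressWarnings(unipolar_recording(...))
}

# a clean biphasic (RS) test wave centered so its steepest negative slope
# falls at `center_ms`
biphasic_wave <- function(n, sampling_rate, center_ms, amp = 1,
                          r_frac = 0.45, sigma_ms = 4) {
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  tau <- t_ms - center_ms
  amp * (r_frac * exp(-(tau + sigma_ms)^2 / (2 * sigma_ms^2)) -
           (1 - r_frac) * exp(-(tau - sigma_ms)^2 / (2 * sigma_ms^2)))
}

# monophasic negative (QS) wave with steepest negative slope at `center_ms`
qs_wave <- function(n, sampling_rate, center_ms, amp = 1, sigma_ms = 4) {
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  -amp * exp(-(t_ms - center_ms - sigma_ms)^2 / (2 * sigma_ms^2))
}

# tiny 3 x 3 grid array (custom kind) for hand-built detector tests:
# ids g11..g33 on a 10 mm grid, 4-connected
grid_array <- function(spacing = 10) {
  ids <- outer(1:3, 1:3, function(i, j) sprintf("g%d%d", i, j))
  electrodes <- tibble::tibble(
    electrode_id = as.vector(ids),
    spline = rep(1:3, times = 3),
    index = rep(1:3, each = 3),
    x = spacing * rep(1:3, times = 3),
    y = spacing * rep(1:3, each = 3),
    z = 0
  )
  adjacency <- list()
  for (i in 1:3) for (j in 1:3) {
    nb <- character()
    if (i > 1) nb <- c(nb, sprintf("g%d%d", i - 1, j))
    if (i < 3) nb <- c(nb, sprintf("g%d%d", i + 1, j))
    if (j > 1) nb <- c(nb, sprintf("g%d%d", i, j - 1))
    if (j < 3) nb <- c(nb, sprintf("g%d%d", i, j + 1))
    adjacency[[sprintf("g%d%d", i, j)]] <- nb
  }
  electrode_array(electrodes, adjacency, "custom")
}

# hand-built egm_annotation from an event table (all channels pass quality)
manual_annotation <- function(events, ids, duration = 30,
                              params = annotate_params()) {
  events <- classify_morphology(events)
  channels <- tibble::tibble(
    electrode_id = ids,
    passed = TRUE, reasons = replicate(length(ids), character(),
                                       simplify = FALSE),
    beat_count = vapply(ids, function(i) sum(events$electrode_id == i),
                        integer(1)),
    snr = Inf, p2p_mv = 1, dominant_frequency = 7
  )
  structure(list(events = events[events$electrode_id %in% ids, ],
                 channels = channels, params = params,
                 sampling_rate = 1000, duration = duration),
            class = "egm_annotation")
}

# independent brute-force count of qualifying consecutive-focal runs,
# used as an oracle against the detector's run bookkeeping
oracle_count_runs <- function(lats, focal, gap_factor, min_consecutive) {
  if (length(lats) < 2) return(integer())
  max_gap <- gap_factor * stats::median(diff(lats))
  runs <- integer()
  i <- 1
  while (i <= length(lats)) {
    if (!focal[i]) { i <- i + 1; next }
    len <- 1
    while (i + len <= length(lats) && focal[i + len] &&
           (lats[i + len] - lats[i + len - 1]) <= max_gap) len <- len + 1
    runs <- c(runs, len)
    i <- i + len
  }
  runs[runs >= min_consecutive]
}
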