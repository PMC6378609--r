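#' Activation source schedules
#'
#' Kinematic descriptions of the activation patterns the simulator can
#' instantiate on the atrial surface:
#' \itemize{
#'   \item `schedule_focal()` - a point source firing at listed times, with
#'     radial (geodesic) spread at constant conduction velocity;
#'   \item `schedule_planar()` - a planar wavefront sweeping the surface
#'     along a direction at each firing time;
#'   \item `schedule_reentry()` - continuous rotation around a circuit
#'     (macro- or micro-reentry depending on the circuit radius), with
#'     radial delay outside the core.
#' }
#'
#' @param origin 3-vector (mm), source location on the surface.
#' @param firing_times Increasing numeric vector of firing times (ms).
#' @param cv Conduction velocity (mm/ms), in `[0.2, 2]`.
#' @return A `source_schedule` object.
#' @export
schedule_focal <- function(origin, firing_times, cv = 1) {
  check_cv(cv)
  firing_times <- as.numeric(firing_times)
  if (is.unsorted(firing_times, strictly = TRUE)) {
    abort("firing_times must be strictly increasing",
          class = "focalroi_error_simulate")
  }
  structure(list(source_type = "focal", origin = as.numeric(origin),
                 firing_times = firing_times, cv = cv),
            class = "source_schedule")
}

#' @rdname schedule_focal
#' @param direction 3-vector, propagation direction (normalized internally).
#' @export
schedule_planar <- function(direction, firing_times, cv = 1) {
  check_cv(cv)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm <= 0) abort("direction must be non-zero",
                      class = "focalroi_error_simulate")
  structure(list(source_type = "planar", direction = direction / nrm,
                 firing_times = as.numeric(firing_times), cv = cv),
            class = "source_schedule")
}

#' @rdname schedule_focal
#' @param center 3-vector (mm), circuit center on the surface.
#' @param circuit_radius_mm Circuit (core) radius in mm; ~5 mm models
#'   micro-reentry, ~20 mm macro-reentry.
#' @param period_ms Rotation period (ms, >= 100).
#' @param t_end_ms Last time (ms) for which rotations are generated.
#' @export
schedule_reentry <- function(center, circuit_radius_mm, period_ms,
                             cv = 1, t_end_ms = 30000) {
  check_cv(cv)
  if (period_ms < 100) abort("reentry period must be >= 100 ms",
                             class = "focalroi_error_simulate")
  structure(list(source_type = "reentry", center = as.numeric(center),
                 circuit_radius_mm = circuit_radius_mm,
                 period_ms = period_ms, cv = cv, t_end_ms = t_end_ms),
            class = "source_schedule")
}

check_cv <- function(cv) {
  if (!is.numeric(cv) || cv < 0.2 || cv > 2) {
    abort("conduction velocity must be in [0.2, 2] mm/ms",
          class = "focalroi_error_simulate")
  }
}

#' Propagate a schedule to electrode activation times
#'
#' Kinematic (eikonal-style) propagation on a spherical surface: focal
#' sources activate each electrode `geodesic / cv` after each firing; planar
#' wavefronts activate along the projection on the propagation direction;
#' reentry activates by rotation phase plus radial delay outside the core.
#'
#' @param schedule A `source_schedule`.
#' @param surface A spherical `atrial_surface`.
#' @param positions n x 3 matrix of electrode positions (mm) with electrode
#'   ids as row names; electrodes must lie on or near the surface.
#' @return Tibble `electrode_id`, `time_ms` (one row per activation),
#'   ordered by electrode then time.
#' @export
propagate <- function(schedule, surface, positions) {
  ids <- rownames(positions)
  diam <- 2 * max(surface$semi_axes)
  ctr <- matrix(surface$center, nrow(positions), 3, byrow = TRUE)
  if (any(sqrt(rowSums((positions - ctr)^2)) > diam + 1e-9)) {
    abort("electrode positions lie farther than the surface diameter from its center",
          class = "focalroi_error_simulate")
  }
  if (schedule$source_type == "focal") {
    delay <- geodesic_distance(surface, schedule$origin, positions) / schedule$cv
    out <- purrr::map_dfr(seq_along(ids), function(i) {
      tibble(electrode_id = ids[i], time_ms = schedule$firing_times + delay[i])
    })
  } else if (schedule$source_type == "planar") {
    proj <- positions %*% schedule$direction
    delay <- (proj - min(proj)) / schedule$cv
    out <- purrr::map_dfr(seq_along(ids), function(i) {
      tibble(electrode_id = ids[i], time_ms = schedule$firing_times + delay[i])
    })
  } else {
    r <- surface$semi_axes[1]
    n <- (project_to_surface(surface, schedule$center)[1, ] - surface$center) / r
    u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * n) * n; u <- u / sqrt(sum(u^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    w <- sweep(positions, 2, surface$center)
    alpha <- atan2(w %*% v, w %*% u)
    alpha <- (alpha + 2 * pi) %% (2 * pi)
    dist_c <- geodesic_distance(surface, schedule$center, positions)
    radial_delay <- pmax(0, dist_c - schedule$circuit_radius_mm) / schedule$cv
    n_rot <- ceiling(schedule$t_end_ms / schedule$period_ms) + 1
    out <- purrr::map_dfr(seq_along(ids), function(i) {
      t0 <- (alpha[i] / (2 * pi)) * schedule$period_ms + radial_delay[i]
      times <- t0 + schedule$period_ms * (seq_len(n_rot) - 1)
      tibble(electrode_id = ids[i],
             time_ms = times[times <= schedule$t_end_ms])
    })
  }
  dplyr::arrange(out, .data$electrode_id, .data$time_ms)
}

#' Morphology model applied to propagated activations
#'
#' Converts activation times into renderable events with a unipolar
#' morphology: electrodes within `qs_radius_mm` (geodesic) of the firing
#' origin receive a monophasic negative (QS) template; remote electrodes
#' receive an RS template with R fraction drawn from `rs_range`. Amplitude
#' falls off with geodesic distance `d` from the origin as `d0 / (d0 + d)`.
#' Without an origin (planar wavefronts, reentry) every electrode is RS at
#' full amplitude.
#'
#' @param times Tibble `electrode_id`, `time_ms` from [propagate()].
#' @param surface The `atrial_surface`.
#' @param positions Electrode position matrix (rows named by id).
#' @param origin Firing origin (3-vector, mm) or `NULL`.
#' @param morph Morphology model parameters, see [morph_model()].
#' @return Tibble `electrode_id`, `time_ms`, `r_target`, `amp_mv`.
#' @export
morph_events <- function(times, surface, positions, origin = NULL,
                         morph = morph_model()) {
  n <- nrow(times)
  if (is.null(origin)) {
    r_target <- runif(n, morph$rs_range[1], morph$rs_range[2])
    amp <- rep(morph$amp_mv, n)
  } else {
    d <- setNames(geodesic_distance(surface, origin, positions),
                  rownames(positions))[times$electrode_id]
    qs <- d < morph$qs_radius_mm
    r_target <- ifelse(qs, 0, runif(n, morph$rs_range[1], morph$rs_range[2]))
    amp <- morph$amp_mv * morph$atten_d0_mm / (morph$atten_d0_mm + d)
  }
  dplyr::mutate(times, r_target = r_target, amp_mv = amp)
}

#' Morphology model parameters
#'
#' @param qs_radius_mm Electrodes within this geodesic distance of a focal
#'   origin record a QS (monophasic negative) wave; default 5 mm.
#' @param amp_mv Template amplitude at the source (mV).
#' @param width_ms Template width (the Gaussian lobes have standard
#'   deviation `width_ms / 4`).
#' @param rs_range R-fraction range for remote (RS) activations.
#' @param atten_d0_mm Distance-attenuation scale: amplitude falls as
#'   `d0 / (d0 + d)`.
#' @return Named list.
#' @export
morph_model <- function(qs_radius_mm = 5, amp_mv = 1, width_ms = 16,
                        rs_range = c(0.35, 0.55), atten_d0_mm = 20) {
  list(qs_radius_mm = qs_radius_mm, amp_mv = amp_mv, width_ms = width_ms,
       rs_range = rs_range, atten_d0_mm = atten_d0_mm)
}

#' Render events to unipolar electrogram traces
#'
#' Each event contributes a template wave centered on its activation time:
#' QS events (`r_target < 0.05`) a monophasic negative Gaussian whose
#' steepest negative slope falls exactly at the activation time; RS events a
#' biphasic wave (positive lobe before, negative after). Overlapping waves
#' superpose linearly.
#'
#' @param events Tibble `electrode_id`, `time_ms`, `r_target`, `amp_mv`.
#' @param electrode_ids Channels to render (columns of the output).
#' @param sampling_rate Hz.
#' @param duration_s Trace length (s).
#' @param width_ms Template width (ms).
#' @return Numeric matrix, samples x electrodes (mV).
#' @export
render_egm <- function(events, electrode_ids, sampling_rate, duration_s,
                       width_ms = 16) {
  n <- round(sampling_rate * duration_s)
  sigma_ms <- width_ms / 4
  sg <- sigma_ms * sampling_rate / 1000
  delta <- sg
  half <- ceiling(4 * sg + delta)
  tt <- seq(-half, half)
  traces <- matrix(0, n, length(electrode_ids),
                   dimnames = list(NULL, electrode_ids))
  for (j in seq_along(electrode_ids)) {
    ev <- events[events$electrode_id == electrode_ids[j], ]
    if (nrow(ev) == 0) next
    tr <- numeric(n)
    for (k in seq_len(nrow(ev))) {
      i0 <- round(ev$time_ms[k] * sampling_rate / 1000) + 1
      idx <- i0 + tt
      ok <- idx >= 1 & idx <= n
      if (!any(ok)) next
      r <- ev$r_target[k]; a <- ev$amp_mv[k]
      wave <- if (r < 0.05) {
        -a * exp(-(tt - sg)^2 / (2 * sg^2))
      } else {
        a * (r * exp(-(tt + delta)^2 / (2 * sg^2)) -
               (1 - r) * exp(-(tt - delta)^2 / (2 * sg^2)))
      }
      tr[idx[ok]] <- tr[idx[ok]] + wave[ok]
    }
    traces[, j] <- tr
  }
  traces
}

#' Add measurement noise to rendered traces
#'
#' White Gaussian noise plus a mains (power-line) tone, injected before
#' filtering so the notch filter is exercised.
#'
#' @param traces Samples x electrodes matrix (mV).
#' @param sampling_rate Hz.
#' @param noise_rms_mv White-noise RMS (mV).
#' @param mains_hz,mains_amp_mv Mains tone frequency and amplitude (random
#'   phase per channel).
#' @return Matrix of the same shape.
#' @export
add_noise <- function(traces, sampling_rate, noise_rms_mv,
                      mains_hz = 60, mains_amp_mv = 0.2) {
  n <- nrow(traces)
  t_s <- (seq_len(n) - 1) / sampling_rate
  for (j in seq_len(ncol(traces))) {
    phase <- runif(1, 0, 2 * pi)
    traces[, j] <- traces[, j] + rnorm(n, 0, noise_rms_mv) +
      mains_amp_mv * sin(2 * pi * mains_hz * t_s + phase)
  }
  traces
}

#' Draw driver run lengths for a 30-second window
#'
#' Number of occurrences is Poisson with the configured recurrence; each
#' run's length is `2 + Poisson(run_length_mean - 2)` so every run meets the
#' two-repetition driver definition.
#'
#' @param recurrence_per_30s Mean occurrences per 30 s.
#' @param run_length_mean Mean consecutive repetitions per occurrence
#'   (>= 2).
#' @return Integer vector of run lengths (possibly empty).
#' @export
draw_driver_runs <- function(recurrence_per_30s = 11, run_length_mean = 3) {
  if (run_length_mean < 2) abort("run_length_mean must be >= 2",
                                 class = "focalroi_error_simulate")
  n <- rpois(1, recurrence_per_30s)
  if (n == 0) return(integer())
  2L + rpois(n, run_length_mean - 2)
}

default_sim_params <- function() {
  list(sampling_rate = 1000, duration_s = 30, cv = 1,
       cycle_length_ms = 250, source_electrode = "C4",
       circuit_radius_mm = 15, direction = c(1, 0, 0),
       base_cycle_length_ms = 145, cycle_jitter_sd_ms = 10,
       recurrence_per_30s = 11, run_length_mean = 3,
       timing_jitter_sd_ms = 2, snr = 10, mains_amp_mv = 0.2,
       morph = morph_model())
}

#' Simulate a 30-second unipolar recording with ground truth
#'
#' Scenarios mirror the validation arms of the detector:
#' \describe{
#'   \item{`focal_at`}{regular focal tachycardia firing from one electrode
#'     site at a fixed cycle length (default 250 ms).}
#'   \item{`reentrant_at`}{macro-/micro-reentrant tachycardia rotating
#'     around a circuit (no focal origin, RS morphology everywhere).}
#'   \item{`planar_at`}{regular planar wavefronts (distant source).}
#'   \item{`af_with_driver`}{fibrillation-like activity: disorganized planar
#'     wavelets from random directions at a jittered base cycle length
#'     (default 145 ms), interleaved with an intermittent focal driver
#'     firing in runs (default ~11 occurrences per 30 s, mean run length
#'     3).}
#'   \item{`af_no_driver`}{the disorganized background only.}
#' }
#' Noise (white, RMS `amp / snr`) and a mains tone are added pre-filter.
#' With a fixed seed the output is bit-for-bit reproducible.
#'
#' @param scenario Scenario name, see above.
#' @param array An `electrode_array` (default 64-electrode basket on the
#'   default surface).
#' @param surface A spherical `atrial_surface`.
#' @param params Named list overriding the scenario defaults: sampling rate,
#'   duration, conduction velocity `cv`, `cycle_length_ms`,
#'   `source_electrode`, `circuit_radius_mm`, `base_cycle_length_ms`,
#'   `cycle_jitter_sd_ms`, `recurrence_per_30s`, `run_length_mean`,
#'   `timing_jitter_sd_ms`, `snr`, `mains_amp_mv`, `morph` (see
#'   [morph_model()]).
#' @param seed Integer RNG seed.
#' @return List with `recording` (a `unipolar_recording`) and `truth` (list:
#'   scenario, seed, drivers with site/firing times/run lengths, and the
#'   full event table).
#' @export
simulate_recording <- function(scenario = c("focal_at", "reentrant_at",
                                            "planar_at", "af_with_driver",
                                            "af_no_driver"),
                               array = NULL, surface = atrial_surface(),
                               params = list(), seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(array)) array <- make_basket_array(surface$semi_axes[1],
                                                 surface$center)
  p <- utils::modifyList(default_sim_params(), params)
  set.seed(seed)
  pos <- electrode_positions(array)
  dur_ms <- p$duration_s * 1000
  drivers <- list()

  if (scenario == "focal_at") {
    origin <- pos[p$source_electrode, ]
    firings <- seq(10, dur_ms - 1, by = p$cycle_length_ms)
    times <- propagate(schedule_focal(origin, firings, p$cv), surface, pos)
    events <- morph_events(times, surface, pos, origin, p$morph)
    drivers <- list(list(electrode_id = p$source_electrode,
                         xyz = as.numeric(origin), firing_times = firings,
                         runs = length(firings)))
  } else if (scenario == "reentrant_at") {
    center <- pos[p$source_electrode, ]
    sch <- schedule_reentry(center, p$circuit_radius_mm, p$cycle_length_ms,
                            p$cv, dur_ms)
    times <- propagate(sch, surface, pos)
    events <- morph_events(times, surface, pos, NULL, p$morph)
  } else if (scenario == "planar_at") {
    firings <- seq(10, dur_ms - 1, by = p$cycle_length_ms)
    times <- propagate(schedule_planar(p$direction, firings, p$cv),
                       surface, pos)
    events <- morph_events(times, surface, pos, NULL, p$morph)
  } else {
    cl <- pmax(100, rnorm(ceiling(dur_ms / (p$base_cycle_length_ms - 30)),
                          p$base_cycle_length_ms, p$cycle_jitter_sd_ms))
    onsets <- 50 + cumsum(c(0, cl))
    onsets <- onsets[onsets < dur_ms - 50]
    n_cyc <- length(onsets)
    is_driver <- rep(FALSE, n_cyc)
    if (scenario == "af_with_driver") {
      runs <- draw_driver_runs(p$recurrence_per_30s, p$run_length_mean)
      runs <- allocate_runs(runs, n_cyc)
      for (r in runs$starts_lens) is_driver[r[1]:(r[1] + r[2] - 1)] <- TRUE
      origin <- pos[p$source_electrode, ]
    }
    # vectorized cycle-by-cycle assembly (one wavefront per cycle)
    ids <- rownames(pos)
    n_el <- length(ids)
    if (scenario == "af_with_driver") {
      gdist <- geodesic_distance(surface, origin, pos)
      drv_delay <- gdist / p$cv
      drv_amp <- p$morph$amp_mv * p$morph$atten_d0_mm /
        (p$morph$atten_d0_mm + gdist)
      drv_qs <- gdist < p$morph$qs_radius_mm
    }
    chunks <- vector("list", n_cyc)
    for (i in seq_len(n_cyc)) {
      if (is_driver[i]) {
        chunks[[i]] <- list(time_ms = onsets[i] + drv_delay,
                            r_target = ifelse(drv_qs, 0,
                                              runif(n_el, p$morph$rs_range[1],
                                                    p$morph$rs_range[2])),
                            amp_mv = drv_amp)
      } else {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        proj <- as.numeric(pos %*% dir)
        chunks[[i]] <- list(
          time_ms = onsets[i] + (proj - min(proj)) / p$cv +
            rnorm(n_el, 0, p$timing_jitter_sd_ms),
          r_target = runif(n_el, p$morph$rs_range[1], p$morph$rs_range[2]),
          amp_mv = rep(p$morph$amp_mv, n_el))
      }
    }
    events <- tibble(
      electrode_id = rep(ids, n_cyc),
      time_ms = unlist(lapply(chunks, `[[`, "time_ms"), use.names = FALSE),
      r_target = unlist(lapply(chunks, `[[`, "r_target"), use.names = FALSE),
      amp_mv = unlist(lapply(chunks, `[[`, "amp_mv"), use.names = FALSE))
    if (scenario == "af_with_driver" && length(runs$lens)) {
      drivers <- list(list(electrode_id = p$source_electrode,
                           xyz = as.numeric(pos[p$source_electrode, ]),
                           firing_times = onsets[is_driver],
                           runs = runs$lens))
    }
  }

  traces <- render_egm(events, rownames(pos), p$sampling_rate, p$duration_s,
                       p$morph$width_ms)
  noise_rms <- if (is.finite(p$snr) && p$snr > 0) p$morph$amp_mv / p$snr else 0
  if (noise_rms > 0 || p$mains_amp_mv > 0) {
    traces <- add_noise(traces, p$sampling_rate, noise_rms,
                        mains_amp_mv = p$mains_amp_mv)
  }
  rec <- unipolar_recording(traces, p$sampling_rate, array,
                            recording_id = sprintf("%s_seed%s", scenario,
                                                   format(seed)))
  list(recording = rec,
       truth = list(scenario = scenario, seed = seed, drivers = drivers,
                    events = events))
}

# place runs into non-overlapping cycle blocks with background in between:
# the cycle axis is split into one segment per run and each run lands at a
# uniform offset inside its segment, keeping >= 1 background cycle margin
allocate_runs <- function(runs, n_cyc) {
  if (!length(runs)) return(list(lens = integer(), starts_lens = list()))
  n_runs <- length(runs)
  seg <- floor(n_cyc / n_runs)
  lens <- pmin(runs, max(2, seg - 2))
  starts_lens <- list()
  for (k in seq_len(n_runs)) {
    lo <- (k - 1) * seg + 2
    hi <- k * seg - lens[k]
    if (hi < lo) { lens[k] <- NA; next }
    start <- if (hi > lo) sample(lo:hi, 1) else lo
    starts_lens[[length(starts_lens) + 1]] <- c(start, lens[k])
  }
  keep <- !is.na(lens)
  list(lens = as.integer(lens[keep]), starts_lens = starts_lens)
}

#' Write / read a simulation truth sidecar
#'
#' JSON sidecar (`<prefix>.truth.json`) recording scenario, seed and the
#' true driver sites with firing times and run lengths.
#'
#' @param truth The `truth` element of [simulate_recording()] output.
#' @param prefix File path prefix (as for [save_bundle()]).
#' @return `write_truth()` the path, invisibly; `read_truth()` the list.
#' @export
write_truth <- function(truth, prefix) {
  path <- paste0(prefix, ".truth.json")
  out <- list(scenario = truth$scenario, seed = truth$seed,
              drivers = lapply(truth$drivers, function(d) {
                list(electrode_id = d$electrode_id, xyz = d$xyz,
                     firing_times = d$firing_times, runs = d$runs)
              }))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  jsonlite::fromJSON(paste0(prefix, ".truth.json"), simplifyVector = FALSE)
}
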