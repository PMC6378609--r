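#' Default ROI detection parameters
#'
#' @param min_consecutive Minimum consecutive focal repetitions for a site
#'   to qualify (default 2).
#' @param assoc_window_ms Forward window in which a neighbor's activation is
#'   associated with a candidate activation (ms).
#' @param lead_window_ms Backward window: neighbor activations up to this
#'   long before the candidate are still bound (with negative offset), so a
#'   candidate that is not actually first cannot appear to lead (ms).
#' @param min_valid_neighbors Minimum quality-passed neighbors with a bound
#'   activation for a candidate to be eligible.
#' @param lead_tol_ms Leading is strict: every bound neighbor offset must
#'   exceed this tolerance (default 0 ms, ties are not leading).
#' @param gap_factor A run of consecutive focal activations is broken when
#'   the gap between successive firings exceeds `gap_factor` times the
#'   electrode's median cycle length.
#' @param merge_radius_mm Sites closer than this are merged (default 10 mm,
#'   matching the 1 cm correlation rule).
#' @return Named list of parameters.
#' @export
roi_params <- function(min_consecutive = 2, assoc_window_ms = 60,
                       lead_window_ms = 30, min_valid_neighbors = 3,
                       lead_tol_ms = 0, gap_factor = 1.5,
                       merge_radius_mm = 10) {
  list(min_consecutive = min_consecutive, assoc_window_ms = assoc_window_ms,
       lead_window_ms = lead_window_ms,
       min_valid_neighbors = min_valid_neighbors, lead_tol_ms = lead_tol_ms,
       gap_factor = gap_factor, merge_radius_mm = merge_radius_mm)
}

# earliest neighbor LAT strictly inside (t - back, t + fwd]; NA when none
bind_neighbor_lat <- function(t, neighbor_lats, back, fwd) {
  pos <- findInterval(t - back, neighbor_lats) + 1
  out <- rep(NA_real_, length(t))
  ok <- pos <= length(neighbor_lats)
  cand <- ifelse(ok, neighbor_lats[pmin(pos, length(neighbor_lats))], NA_real_)
  ok <- ok & cand <= t + fwd
  out[ok] <- cand[ok]
  out
}

#' Associate a candidate activation with its neighbors' activations
#'
#' For each quality-passed neighbor of the candidate electrode, binds the
#' earliest activation with LAT in `(t - lead_window_ms, t +
#' assoc_window_ms]`. Neighbors that fired slightly before the candidate are
#' bound with a negative offset (so the candidate is not leading); neighbors
#' with no activation in the window are excluded from the valid count.
#'
#' @param events Quality-gated event tibble (from [annotate_recording()]).
#' @param adjacency Neighbor graph (named list), e.g. [neighbor_graph()].
#' @param electrode Candidate electrode id.
#' @param lat Candidate LAT (ms).
#' @param params See [roi_params()].
#' @return List with `neighbors` (tibble: `electrode_id`, `lat_ms`,
#'   `offset_ms`) and `valid_neighbor_count`.
#' @export
associate_cycle <- function(events, adjacency, electrode, lat,
                            params = roi_params()) {
  nbs <- adjacency[[electrode]]
  rows <- purrr::map_dfr(nbs, function(nb) {
    nl <- sort(events$lat_ms[events$electrode_id == nb])
    if (!length(nl)) return(NULL)
    bound <- bind_neighbor_lat(lat, nl, params$lead_window_ms,
                               params$assoc_window_ms)
    if (is.na(bound)) return(NULL)
    tibble(electrode_id = nb, lat_ms = bound, offset_ms = bound - lat)
  })
  list(neighbors = rows, valid_neighbor_count = nrow(rows))
}

#' Test one activation against the focal criteria
#'
#' A counted focal activation must (1) show QS morphology and (2) be earlier
#' than every bound neighboring activation (strictly). Candidates with too
#' few valid neighbors are ineligible, which is distinct from "not focal".
#'
#' @param context Result of [associate_cycle()].
#' @param qs Logical: does the candidate event carry QS morphology?
#' @param params See [roi_params()].
#' @return List with `status` (`"focal"`, `"not_focal"` or `"ineligible"`),
#'   `qs` and `leading`.
#' @export
focal_test <- function(context, qs, params = roi_params()) {
  if (context$valid_neighbor_count < params$min_valid_neighbors) {
    return(list(status = "ineligible", qs = qs, leading = NA))
  }
  leading <- all(context$neighbors$offset_ms > params$lead_tol_ms)
  list(status = if (qs && leading) "focal" else "not_focal",
       qs = qs, leading = leading)
}

# per-electrode focal flags for all events, vectorized over neighbors
focal_flags_for_electrode <- function(events, adjacency, electrode, params) {
  ev <- events[events$electrode_id == electrode, ]
  ev <- ev[order(ev$lat_ms), ]
  n <- nrow(ev)
  if (n == 0) return(ev)
  nbs <- adjacency[[electrode]]
  offsets <- matrix(NA_real_, n, length(nbs))
  for (k in seq_along(nbs)) {
    nl <- sort(events$lat_ms[events$electrode_id == nbs[k]])
    if (!length(nl)) next
    offsets[, k] <- bind_neighbor_lat(ev$lat_ms, nl, params$lead_window_ms,
                                      params$assoc_window_ms) - ev$lat_ms
  }
  valid <- rowSums(!is.na(offsets))
  min_off <- suppressWarnings(apply(offsets, 1, min, na.rm = TRUE))
  leading <- is.finite(min_off) & min_off > params$lead_tol_ms
  ev$eligible <- valid >= params$min_valid_neighbors
  ev$leading <- leading
  ev$focal <- ev$eligible & leading & ev$morphology == "QS"
  ev
}

# run lengths of consecutive focal activations with a gap rule
focal_runs <- function(lats, focal, gap_factor) {
  if (length(lats) < 2) return(list(runs = integer(), bounds = list()))
  max_gap <- gap_factor * median(diff(lats))
  runs <- integer(); bounds <- list()
  cur <- 0L; start <- NA_real_; last <- NA_real_
  flush <- function() {
    if (cur > 0) {
      runs[[length(runs) + 1]] <<- cur
      bounds[[length(bounds) + 1]] <<- c(start, last)
    }
    cur <<- 0L
  }
  for (i in seq_along(lats)) {
    if (!focal[i]) { flush(); next }
    if (cur > 0 && (lats[i] - last) > max_gap) flush()
    if (cur == 0) start <- lats[i]
    cur <- cur + 1L
    last <- lats[i]
  }
  flush()
  list(runs = runs, bounds = bounds)
}

#' Detect ROI sites in an annotated recording
#'
#' The core detector. Per electrode, each activation is tested against the
#' focal criteria (QS morphology and leading all bound neighbors); runs of
#' consecutive focal activations are counted, broken by any non-focal
#' activation or by an inter-firing gap exceeding `gap_factor` times the
#' electrode's median cycle length. An electrode becomes an ROI site when at
#' least one run reaches `min_consecutive` repetitions. Sites within
#' `merge_radius_mm` of a stronger site are merged into it (the electrode
#' with most occurrences is kept; runs and occurrences are pooled).
#'
#' @param annotation An `egm_annotation` (quality-gated).
#' @param array The `electrode_array` the recording was made with.
#' @param params See [roi_params()].
#' @param adjacency Optional neighbor graph; defaults to the array's
#'   structural adjacency.
#' @return A tibble of class `roi_sites`: `electrode_id`, `x`, `y`, `z`,
#'   `occurrences`, `max_run`, `runs` (list column of counted run lengths),
#'   `first_ms`, `last_ms`.
#' @export
detect_roi <- function(annotation, array, params = roi_params(),
                       adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- array$adjacency
  events <- annotation$events
  empty <- tibble(electrode_id = character(), x = numeric(), y = numeric(),
                  z = numeric(), occurrences = integer(), max_run = integer(),
                  runs = list(), first_ms = numeric(), last_ms = numeric())
  as_roi_sites <- function(x) structure(x, class = c("roi_sites", class(empty)),
                                        array = array, params = params)
  if (nrow(events) == 0) return(as_roi_sites(empty))
  med_cl <- median(diff(sort(events$lat_ms[events$electrode_id ==
                                             events$electrode_id[1]])))
  if (is.finite(med_cl) && annotation$duration * 1000 < 2 * med_cl) {
    warn("recording shorter than two cycles; no ROI can be counted",
         class = "focalroi_warn_short_recording")
    return(as_roi_sites(empty))
  }
  pos <- electrode_positions(array)
  sites <- purrr::map_dfr(unique(events$electrode_id), function(id) {
    ev <- focal_flags_for_electrode(events, adjacency, id, params)
    if (!any(ev$focal)) return(NULL)
    fr <- focal_runs(ev$lat_ms, ev$focal, params$gap_factor)
    counted <- fr$runs >= params$min_consecutive
    if (!any(counted)) return(NULL)
    bounds <- do.call(rbind, fr$bounds[counted])
    tibble(electrode_id = id, x = pos[id, 1], y = pos[id, 2], z = pos[id, 3],
           occurrences = sum(counted), max_run = max(fr$runs[counted]),
           runs = list(fr$runs[counted]),
           first_ms = min(bounds[, 1]), last_ms = max(bounds[, 2]))
  })
  if (is.null(sites) || nrow(sites) == 0) return(as_roi_sites(empty))
  sites <- merge_sites(sites, params$merge_radius_mm)
  sites <- dplyr::arrange(sites, dplyr::desc(.data$occurrences),
                          .data$electrode_id)
  as_roi_sites(sites)
}

# greedy merge: strongest site absorbs all sites strictly within radius
merge_sites <- function(sites, merge_radius_mm) {
  sites <- sites[order(-sites$occurrences, sites$electrode_id), ]
  keep <- list()
  while (nrow(sites) > 0) {
    top <- sites[1, ]
    d <- sqrt((sites$x - top$x)^2 + (sites$y - top$y)^2 + (sites$z - top$z)^2)
    absorb <- d < merge_radius_mm
    grp <- sites[absorb, ]
    top$occurrences <- sum(grp$occurrences)
    top$max_run <- max(grp$max_run)
    top$runs <- list(unlist(grp$runs))
    top$first_ms <- min(grp$first_ms)
    top$last_ms <- max(grp$last_ms)
    keep[[length(keep) + 1]] <- top
    sites <- sites[!absorb, ]
  }
  dplyr::bind_rows(keep)
}

#' Verify radial spread from a source activation
#'
#' Checks the wavefront signature of a focal discharge: all first-ring
#' neighbors activate after the source, and the mean second-ring delay
#' exceeds the mean first-ring delay (monotone outward timing).
#'
#' @param annotation An `egm_annotation`.
#' @param array The `electrode_array`.
#' @param source_electrode Source electrode id.
#' @param lat Source activation time (ms).
#' @param params See [roi_params()]; the forward association window is
#'   doubled for the second ring.
#' @return List with `radial` (logical), `ring1_offsets_ms`,
#'   `ring2_offsets_ms` and `insufficient_coverage`.
#' @export
radial_spread_test <- function(annotation, array, source_electrode, lat,
                               params = roi_params()) {
  adjacency <- array$adjacency
  ring1 <- adjacency[[source_electrode]]
  ring2 <- setdiff(unique(unlist(adjacency[ring1])),
                   c(ring1, source_electrode))
  events <- annotation$events
  get_offsets <- function(ids, fwd) {
    off <- purrr::map_dbl(ids, function(nb) {
      nl <- sort(events$lat_ms[events$electrode_id == nb])
      if (!length(nl)) return(NA_real_)
      bind_neighbor_lat(lat, nl, params$lead_window_ms, fwd) - lat
    })
    off[!is.na(off)]
  }
  o1 <- get_offsets(ring1, params$assoc_window_ms)
  o2 <- get_offsets(ring2, 2 * params$assoc_window_ms)
  insufficient <- length(o1) < params$min_valid_neighbors || length(o2) == 0
  radial <- !insufficient && all(o1 > 0) && mean(o2) > mean(o1)
  list(radial = radial, ring1_offsets_ms = o1, ring2_offsets_ms = o2,
       insufficient_coverage = insufficient)
}

#' Aggregate ROI sites across sequential recordings
#'
#' Greedy centroid clustering of per-recording ROI sites (e.g. from
#' sequential five-spline catheter maps): processing sites from most to
#' fewest occurrences, a site joins the first existing cluster whose
#' centroid lies strictly within `merge_radius_mm`; otherwise it seeds a new
#' cluster. Cluster output pools runs and occurrences and reports the
#' centroid position.
#'
#' @param sites Tibble of per-recording sites with columns `x`, `y`, `z`,
#'   `occurrences`, `runs` (list column), and optionally `recording_id`.
#' @param merge_radius_mm Joining radius (mm), strict.
#' @return Tibble of map-level sites: `site_id`, `x`, `y`, `z`,
#'   `occurrences`, `runs`, `n_recordings`.
#' @export
aggregate_sequential <- function(sites, merge_radius_mm = 10) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0) {
    return(tibble(site_id = integer(), x = numeric(), y = numeric(),
                  z = numeric(), occurrences = integer(), runs = list(),
                  n_recordings = integer()))
  }
  if (!"recording_id" %in% names(sites)) sites$recording_id <- "rec"
  if (!"runs" %in% names(sites)) sites$runs <- list(integer())
  sites <- sites[order(-sites$occurrences), ]
  clusters <- list()
  for (i in seq_len(nrow(sites))) {
    p <- c(sites$x[i], sites$y[i], sites$z[i])
    joined <- FALSE
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (sqrt(sum((p - cl$centroid)^2)) < merge_radius_mm) {
        cl$members <- c(cl$members, i)
        pts <- cbind(sites$x[cl$members], sites$y[cl$members],
                     sites$z[cl$members])
        cl$centroid <- colMeans(pts)
        clusters[[k]] <- cl
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1]] <-
        list(centroid = p, members = i)
  }
  purrr::map_dfr(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    m <- sites[cl$members, ]
    tibble(site_id = k, x = cl$centroid[1], y = cl$centroid[2],
           z = cl$centroid[3], occurrences = sum(m$occurrences),
           runs = list(unlist(m$runs)),
           n_recordings = length(unique(m$recording_id)))
  })
}

#' Run the full detection pipeline on a raw recording
#'
#' Convenience wrapper: filter, annotate, detect.
#'
#' @param recording A raw `unipolar_recording`.
#' @param spec A `filter_spec`.
#' @param ann_params See [annotate_params()].
#' @param params See [roi_params()].
#' @return A `roi_sites` tibble (see [detect_roi()]) with the annotation
#'   attached as attribute `"annotation"`.
#' @export
roi_pipeline <- function(recording, spec = filter_spec(),
                         ann_params = annotate_params(),
                         params = roi_params()) {
  filtered <- filter_unipolar(recording, spec)
  ann <- annotate_recording(filtered, ann_params)
  sites <- detect_roi(ann, recording$array, params)
  attr(sites, "annotation") <- ann
  sites
}
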