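ev_row <- function(id, lat, qs = TRUE) {
  tibble::tibble(electrode_id = id, lat_ms = lat,
                 neg_slope = 0.2, r_amp = if (qs) 0 else 0.4,
                 s_amp = if (qs) 1 else 0.6)
}

test_that("associate_cycle binds neighbor activations in its window", {
  arr <- grid_array()
  ev <- dplyr::bind_rows(
    ev_row("g22", 100),
    ev_row("g12", 108, qs = FALSE), ev_row("g32", 112, qs = FALSE),
    ev_row("g21", 115, qs = FALSE))
  ann <- manual_annotation(ev, arr$electrodes$electrode_id)
  ctx <- associate_cycle(ann$events, arr$adjacency, "g22", 100)
  expect_equal(ctx$valid_neighbor_count, 3)
  expect_setequal(round(ctx$neighbors$offset_ms), c(8, 12, 15))

  # a neighbor firing shortly before is bound with a negative offset
  ev2 <- dplyr::bind_rows(ev, ev_row("g23", 95, qs = FALSE))
  ann2 <- manual_annotation(ev2, arr$electrodes$electrode_id)
  ctx2 <- associate_cycle(ann2$events, arr$adjacency, "g22", 100)
  expect_true(-5 %in% round(ctx2$neighbors$offset_ms))
})

test_that("focal_test applies QS + leading strictly, with eligibility", {
  arr <- grid_array()
  mk_ctx <- function(offsets) {
    list(neighbors = tibble::tibble(
      electrode_id = sprintf("g%d", seq_along(offsets)),
      lat_ms = 100 + offsets, offset_ms = offsets),
      valid_neighbor_count = length(offsets))
  }
  expect_equal(focal_test(mk_ctx(c(5, 12, 40)), qs = TRUE)$status, "focal")
  expect_equal(focal_test(mk_ctx(c(5, 12, 40)), qs = FALSE)$status, "not_focal")
  expect_equal(focal_test(mk_ctx(c(-2, 12, 40)), qs = TRUE)$status, "not_focal")
  expect_equal(focal_test(mk_ctx(c(0, 12, 40)), qs = TRUE)$status, "not_focal")
  expect_equal(focal_test(mk_ctx(c(5, 12)), qs = TRUE)$status, "ineligible")
})

test_that("detect_roi counts consecutive focal repetitions per electrode", {
  arr <- grid_array()
  ids <- arr$electrodes$electrode_id
  # 8 cycles at 200 ms; g22 (center) fires QS and first on cycles 3,4,5 only;
  # on other cycles a sweep makes g22 late and non-QS
  cycles <- (1:8) * 200
  ev <- purrr::map_dfr(seq_along(cycles), function(ci) {
    t0 <- cycles[ci]
    if (ci %in% 3:5) {
      dplyr::bind_rows(
        ev_row("g22", t0),
        purrr::map_dfr(setdiff(ids, "g22"), function(id) {
          i <- as.integer(substr(id, 2, 2)); j <- as.integer(substr(id, 3, 3))
          ev_row(id, t0 + 10 * sqrt((i - 2)^2 + (j - 2)^2), qs = FALSE)
        }))
    } else {
      purrr::map_dfr(ids, function(id) {
        i <- as.integer(substr(id, 2, 2))
        ev_row(id, t0 + 10 * i, qs = FALSE)
      })
    }
  })
  ann <- manual_annotation(ev, ids)
  sites <- detect_roi(ann, arr)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$electrode_id, "g22")
  expect_true(3 %in% sites$runs[[1]])
  expect_gte(sites$occurrences, 1)

  # independent brute-force recount of the focal runs
  flags <- rep(FALSE, 8); flags[3:5] <- TRUE
  oracle <- oracle_count_runs(cycles, flags, 1.5, 2)
  expect_equal(sites$runs[[1]], oracle)
})

test_that("a sweeping planar wave never produces an ROI", {
  arr <- grid_array()
  ids <- arr$electrodes$electrode_id
  ev <- purrr::map_dfr(1:10, function(ci) {
    purrr::map_dfr(ids, function(id) {
      i <- as.integer(substr(id, 2, 2))
      ev_row(id, ci * 200 + 10 * i, qs = FALSE)
    })
  })
  sites <- detect_roi(manual_annotation(ev, ids), arr)
  expect_equal(nrow(sites), 0)
})

test_that("candidates whose neighbors are all quality-failed are ineligible", {
  arr <- grid_array()
  # only g22 passes quality: no neighbor timings exist
  ev <- purrr::map_dfr(1:6, function(ci) ev_row("g22", ci * 200))
  ann <- manual_annotation(ev, "g22")
  sites <- detect_roi(ann, arr)
  expect_equal(nrow(sites), 0)
  ctx <- associate_cycle(ann$events, arr$adjacency, "g22", 200)
  expect_equal(ctx$valid_neighbor_count, 0)
  expect_equal(focal_test(ctx, qs = TRUE)$status, "ineligible")
})

test_that("radial spread requires monotone outward timing", {
  arr <- grid_array()
  ids <- arr$electrodes$electrode_id
  # ring-1 of g22 at +6..+8 ms, ring-2 (corners) around +14 ms
  ev <- dplyr::bind_rows(
    ev_row("g22", 100),
    ev_row("g12", 106, qs = FALSE), ev_row("g32", 107, qs = FALSE),
    ev_row("g21", 107, qs = FALSE), ev_row("g23", 108, qs = FALSE),
    ev_row("g11", 114, qs = FALSE), ev_row("g13", 114, qs = FALSE),
    ev_row("g31", 114, qs = FALSE), ev_row("g33", 114, qs = FALSE))
  ann <- manual_annotation(ev, ids)
  r <- radial_spread_test(ann, arr, "g22", 100)
  expect_true(r$radial)
  expect_false(r$insufficient_coverage)

  # planar pass through the same electrode: one ring-1 neighbor earlier
  ev2 <- ev; ev2$lat_ms[ev2$electrode_id == "g12"] <- 95
  r2 <- radial_spread_test(manual_annotation(ev2, ids), arr, "g22", 100)
  expect_false(r2$radial)

  # corner electrode has no second ring beyond its neighbors' neighbors?
  ann3 <- manual_annotation(ev_row("g11", 100), "g11")
  r3 <- radial_spread_test(ann3, arr, "g11", 100)
  expect_true(r3$insufficient_coverage)
})

test_that("radial spread holds on simulated focal beats but not planar ones", {
  simf <- simulate_recording("focal_at", seed = 31)
  annf <- annotate_recording(filter_unipolar(simf$recording))
  src <- simf$truth$drivers[[1]]$electrode_id
  lat <- sort(annf$events$lat_ms[annf$events$electrode_id == src])[3]
  rf <- radial_spread_test(annf, simf$recording$array, src, lat)
  expect_true(rf$radial)

  simp <- simulate_recording("planar_at", seed = 31)
  annp <- annotate_recording(filter_unipolar(simp$recording))
  latp <- sort(annp$events$lat_ms[annp$events$electrode_id == src])[3]
  rp <- radial_spread_test(annp, simp$recording$array, src, latp)
  expect_false(rp$radial)
})

test_that("sequential aggregation merges nearby sites and pools counts", {
  mk <- function(x, y, z, occ, rid) {
    tibble::tibble(recording_id = rid, x = x, y = y, z = z,
                   occurrences = occ, runs = list(rep(2L, occ)))
  }
  near <- dplyr::bind_rows(mk(0, 0, 0, 3, "r1"), mk(4, 0, 0, 2, "r2"),
                           mk(0, 6, 0, 1, "r3"))
  agg <- aggregate_sequential(near)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$occurrences, 6)
  expect_equal(agg$n_recordings, 3)
  expect_equal(length(agg$runs[[1]]), 6)

  far <- dplyr::bind_rows(mk(0, 0, 0, 3, "r1"), mk(25, 0, 0, 2, "r2"))
  expect_equal(nrow(aggregate_sequential(far)), 2)
  expect_equal(nrow(aggregate_sequential(near[0, ])), 0)
})

test_that("raising min_consecutive never increases the number of sites", {
  sim <- simulate_recording("af_with_driver", seed = 41)
  ann <- annotate_recording(filter_unipolar(sim$recording))
  counts <- purrr::map_int(2:5, function(mc) {
    nrow(detect_roi(ann, sim$recording$array,
                    roi_params(min_consecutive = mc)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is deterministic for identical input", {
  sim <- simulate_recording("focal_at", seed = 51)
  s1 <- roi_pipeline(sim$recording)
  s2 <- roi_pipeline(sim$recording)
  attr(s1, "annotation") <- NULL; attr(s2, "annotation") <- NULL
  expect_identical(s1, s2)
})
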