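test_that("basket array has the standard 8x8 layout on a sphere", {
  arr <- make_basket_array(radius_mm = 25)
  expect_s3_class(arr, "electrode_array")
  expect_equal(nrow(arr$electrodes), 64)
  expect_equal(length(unique(arr$electrodes$spline)), 8)
  pos <- electrode_positions(arr)
  expect_equal(unname(sqrt(rowSums(pos^2))), rep(25, 64), tolerance = 1e-12)

  # brute-force degree enumeration: along-spline links + same-rank links on
  # the two adjacent splines
  deg <- lengths(arr$adjacency)
  interior <- arr$electrodes$electrode_id[arr$electrodes$index %in% 2:7]
  ends <- setdiff(arr$electrodes$electrode_id, interior)
  expect_true(all(deg[interior] == 4))
  expect_true(all(deg[ends] == 3))
})

test_that("scaling the basket radius scales distances but not adjacency", {
  a25 <- make_basket_array(25)
  a50 <- make_basket_array(50)
  expect_identical(a25$adjacency, a50$adjacency)
  d25 <- as.matrix(dist(electrode_positions(a25)))
  d50 <- as.matrix(dist(electrode_positions(a50)))
  expect_equal(d50, 2 * d25, tolerance = 1e-9)
  expect_error(make_basket_array(0), class = "focalroi_error_geometry")
  expect_error(make_basket_array(-3), class = "focalroi_error_geometry")
})

test_that("five-spline array reproduces the 2-6-2 mm spacing", {
  arr <- make_pentaray_array()
  expect_equal(nrow(arr$electrodes), 20)
  expect_equal(length(unique(arr$electrodes$spline)), 5)
  pos <- electrode_positions(arr)
  for (s in 1:5) {
    ids <- sprintf("P%d_%d", s, 1:4)
    gaps <- sqrt(rowSums(diff(pos[ids, ])^2))
    expect_equal(unname(gaps), c(2, 6, 2), tolerance = 1e-9)
  }
  expect_error(make_pentaray_array(orientation = matrix(0, 3, 3)),
               class = "focalroi_error_geometry")
})

test_that("rotating the five-spline array by 72 degrees maps it onto itself", {
  th <- 2 * pi / 5
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  a0 <- electrode_positions(make_pentaray_array())
  a1 <- electrode_positions(make_pentaray_array(orientation = rot))
  # position multisets agree although electrode labels rotate
  key <- function(m) unname(sort(apply(round(m, 9), 1, paste, collapse = ",")))
  expect_identical(key(a0), key(a1))
})

test_that("neighbor graphs: structural, metric, and degenerate radii", {
  basket <- make_basket_array()
  expect_true(all(lengths(neighbor_graph(basket, "structural")) >= 2))

  penta <- make_pentaray_array()
  g7 <- neighbor_graph(penta, "metric", radius_mm = 7)
  # within one spline: 2 mm and 6 mm gaps linked, 8 and 10 mm spans not
  expect_true("P1_2" %in% g7[["P1_1"]])   # 2 mm
  expect_true("P1_3" %in% g7[["P1_2"]])   # 6 mm
  expect_false("P1_3" %in% g7[["P1_1"]])  # 8 mm
  expect_false("P1_4" %in% g7[["P1_1"]])  # 10 mm

  expect_true(all(lengths(neighbor_graph(basket, "metric", 0.001)) == 0))
  expect_error(neighbor_graph(basket, "metric"),
               class = "focalroi_error_geometry")
})

test_that("generated adjacencies are symmetric and irreflexive", {
  for (arr in list(make_basket_array(), make_pentaray_array())) {
    for (id in names(arr$adjacency)) {
      expect_false(id %in% arr$adjacency[[id]])
      for (nb in arr$adjacency[[id]]) {
        expect_true(id %in% arr$adjacency[[nb]])
      }
    }
  }
})

test_that("site correlation uses a strict 10 mm rule and is symmetric", {
  expect_true(correlate_sites(c(1, 2, 3), c(1, 2, 3))$correlated)
  expect_equal(correlate_sites(c(1, 2, 3), c(1, 2, 3))$distance_mm, 0)
  r <- correlate_sites(c(0, 0, 0), c(3, 4, 0))
  expect_true(r$correlated)
  expect_equal(r$distance_mm, 5)
  expect_false(correlate_sites(c(0, 0, 0), c(10, 0, 0))$correlated)
  expect_true(correlate_sites(c(0, 0, 0), c(9.999, 0, 0))$correlated)

  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10); k <- runif(1, 0.1, 5)
    expect_identical(correlate_sites(a, b), correlate_sites(b, a))
    expect_equal(correlate_sites(k * a, k * b)$distance_mm,
                 k * correlate_sites(a, b)$distance_mm, tolerance = 1e-9)
  }
})

test_that("array JSON serialization round-trips", {
  for (arr in list(make_basket_array(31), make_pentaray_array(c(5, -2, 7)))) {
    l <- array_to_list(arr)
    back <- array_from_list(jsonlite::fromJSON(
      jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA),
      simplifyVector = FALSE))
    expect_equal(back$array_kind, arr$array_kind)
    expect_equal(as.data.frame(back$electrodes), as.data.frame(arr$electrodes),
                 tolerance = 1e-12)
    expect_identical(back$adjacency, arr$adjacency)
  }
})

test_that("invalid array definitions are rejected", {
  el <- tibble::tibble(electrode_id = c("a", "b"), spline = 1, index = 1:2,
                       x = c(0, 1), y = 0, z = 0)
  expect_error(electrode_array(el, list(a = "b", b = character())),
               class = "focalroi_error_geometry")   # asymmetric
  expect_error(electrode_array(el, list(a = "a", b = character())),
               class = "focalroi_error_geometry")   # self-edge
  el2 <- el; el2$electrode_id <- c("a", "a")
  expect_error(electrode_array(el2, list(a = character())),
               class = "focalroi_error_geometry")   # duplicate ids
})

test_that("atrial surface: area, projection and geodesics", {
  s <- atrial_surface()
  expect_equal(surface_area(s), 4 * pi * 28.8^2 / 100, tolerance = 1e-12)
  p <- project_to_surface(s, matrix(c(50, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(unname(sqrt(rowSums(p^2))), c(28.8, 28.8), tolerance = 1e-9)
  expect_equal(unname(geodesic_distance(s, c(28.8, 0, 0), c(-28.8, 0, 0))),
               pi * 28.8, tolerance = 1e-9)
  expect_equal(unname(geodesic_distance(s, c(28.8, 0, 0), c(0, 28.8, 0))),
               pi / 2 * 28.8, tolerance = 1e-9)
  expect_error(atrial_surface(c(1, -1, 1)), class = "focalroi_error_geometry")
  expect_error(geodesic_distance(atrial_surface(c(10, 20, 30)),
                                 c(10, 0, 0), c(0, 20, 0)),
               class = "focalroi_error_geometry")
})
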