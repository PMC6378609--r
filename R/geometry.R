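#' Catheter electrode arrays
#'
#' An `electrode_array` describes a mapping catheter: electrode identities,
#' the spline each electrode sits on, its rank along that spline, its 3-D
#' position (mm), and a structural neighbor graph. Two standard layouts are
#' provided: a 64-electrode spherical basket (8 splines of 8 electrodes) and
#' a 20-electrode five-spline star with 2-6-2 mm inter-electrode spacing.
#'
#' @param electrodes A tibble with columns `electrode_id`, `spline`, `index`,
#'   `x`, `y`, `z` (positions in mm).
#' @param adjacency A named list mapping each `electrode_id` to a character
#'   vector of neighbor ids. Must be symmetric and irreflexive.
#' @param array_kind One of `"basket"`, `"pentaray"`, `"custom"`.
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(electrodes, adjacency, array_kind = "custom") {
  array_kind <- match.arg(array_kind, c("basket", "pentaray", "custom"))
  electrodes <- as_tibble(electrodes)
  need <- c("electrode_id", "spline", "index", "x", "y", "z")
  if (!all(need %in% names(electrodes))) {
    abort(paste("electrodes must have columns", paste(need, collapse = ", ")),
          class = "focalroi_error_geometry")
  }
  ids <- electrodes$electrode_id
  if (anyDuplicated(ids)) {
    abort("electrode_ids must be unique", class = "focalroi_error_geometry")
  }
  pos <- as.matrix(electrodes[, c("x", "y", "z")])
  if (!all(is.finite(pos))) {
    abort("all electrode positions must be finite",
          class = "focalroi_error_geometry")
  }
  adjacency <- adjacency[ids]
  names(adjacency) <- ids
  adjacency <- lapply(adjacency, function(v) sort(unique(as.character(v))))
  for (id in ids) {
    nb <- adjacency[[id]]
    if (id %in% nb) abort("self-edges are not allowed",
                          class = "focalroi_error_geometry")
    if (!all(nb %in% ids)) abort("adjacency refers to unknown electrode",
                                 class = "focalroi_error_geometry")
    for (n in nb) {
      if (!(id %in% adjacency[[n]])) {
        abort("adjacency must be symmetric", class = "focalroi_error_geometry")
      }
    }
  }
  structure(list(array_kind = array_kind, electrodes = electrodes,
                 adjacency = adjacency),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array: %s, %d electrodes, %d splines>\n",
              x$array_kind, nrow(x$electrodes),
              length(unique(x$electrodes$spline))))
  invisible(x)
}

#' Electrode positions as a matrix
#'
#' @param array An `electrode_array`.
#' @return A numeric matrix (n x 3, mm) with electrode ids as row names.
#' @export
electrode_positions <- function(array) {
  m <- as.matrix(array$electrodes[, c("x", "y", "z")])
  rownames(m) <- array$electrodes$electrode_id
  m
}

#' Build a spherical basket catheter array
#'
#' Eight splines of eight electrodes (64 total) placed on a sphere.
#' Splines run pole to pole at equally spaced
#' azimuths; electrode ranks 1..8 sit at equally spaced polar angles strictly
#' between the poles (so no two electrodes coincide). Structural adjacency
#' links along-spline neighbors and the same-rank electrodes on the two
#' adjacent splines.
#'
#' @param radius_mm Basket radius in mm (> 0). Default 28.8 mm, sized so the
#'   basket's circular cross-section (26 cm^2) matches a typical planimetered
#'   left-atrial area.
#' @param center 3-vector, basket center (mm).
#' @param n_splines,n_per_spline Layout; defaults 8 x 8 (standard commercial
#'   basket).
#' @return An `electrode_array`.
#' @export
make_basket_array <- function(radius_mm = 28.8, center = c(0, 0, 0),
                              n_splines = 8, n_per_spline = 8) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || !is.finite(radius_mm) ||
      radius_mm <= 0) {
    abort("radius_mm must be a positive number", class = "focalroi_error_geometry")
  }
  stopifnot(length(center) == 3, n_splines >= 3, n_per_spline >= 2)
  grid <- expand.grid(index = seq_len(n_per_spline), spline = seq_len(n_splines))
  theta <- pi * grid$index / (n_per_spline + 1)       # polar angle, poles excluded
  phi <- 2 * pi * (grid$spline - 1) / n_splines       # azimuth per spline
  electrodes <- tibble(
    electrode_id = sprintf("%s%d", LETTERS[grid$spline], grid$index),
    spline = grid$spline,
    index = grid$index,
    x = center[1] + radius_mm * sin(theta) * cos(phi),
    y = center[2] + radius_mm * sin(theta) * sin(phi),
    z = center[3] + radius_mm * cos(theta)
  )
  id_of <- function(s, j) sprintf("%s%d", LETTERS[s], j)
  adjacency <- list()
  for (k in seq_len(nrow(grid))) {
    s <- grid$spline[k]; j <- grid$index[k]
    nb <- character()
    if (j > 1) nb <- c(nb, id_of(s, j - 1))
    if (j < n_per_spline) nb <- c(nb, id_of(s, j + 1))
    # same-rank electrodes on the two adjacent splines (ring neighbors)
    nb <- c(nb, id_of(if (s == 1) n_splines else s - 1, j),
            id_of(if (s == n_splines) 1 else s + 1, j))
    adjacency[[id_of(s, j)]] <- nb
  }
  electrode_array(electrodes, adjacency, "basket")
}

#' Build a five-spline star catheter array
#'
#' Twenty electrodes on five planar splines 72 degrees apart; along each
#' spline the consecutive inter-electrode gaps are 2, 6 and 2 mm (the
#' standard 2-6-2 mm spacing). Structural adjacency links along-spline
#' neighbors only.
#'
#' @param center 3-vector, device center (mm).
#' @param orientation 3x3 rotation matrix giving the device frame (columns =
#'   local x, y, z axes); splines lie in the local x-y plane. Must be
#'   orthonormal with positive determinant.
#' @param inner_radius_mm Distance from the center to the innermost electrode
#'   of each spline (mm).
#' @return An `electrode_array`.
#' @export
make_pentaray_array <- function(center = c(0, 0, 0), orientation = diag(3),
                                inner_radius_mm = 4) {
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      det(orientation) < 0.5) {
    abort("orientation must be a proper 3x3 rotation matrix",
          class = "focalroi_error_geometry")
  }
  radii <- inner_radius_mm + cumsum(c(0, 2, 6, 2))
  grid <- expand.grid(index = 1:4, spline = 1:5)
  ang <- 2 * pi * (grid$spline - 1) / 5
  local <- cbind(radii[grid$index] * cos(ang), radii[grid$index] * sin(ang), 0)
  world <- local %*% t(orientation)
  electrodes <- tibble(
    electrode_id = sprintf("P%d_%d", grid$spline, grid$index),
    spline = grid$spline,
    index = grid$index,
    x = center[1] + world[, 1],
    y = center[2] + world[, 2],
    z = center[3] + world[, 3]
  )
  adjacency <- list()
  for (k in seq_len(nrow(grid))) {
    s <- grid$spline[k]; j <- grid$index[k]
    nb <- character()
    if (j > 1) nb <- c(nb, sprintf("P%d_%d", s, j - 1))
    if (j < 4) nb <- c(nb, sprintf("P%d_%d", s, j + 1))
    adjacency[[sprintf("P%d_%d", s, j)]] <- nb
  }
  electrode_array(electrodes, adjacency, "pentaray")
}

#' Neighbor graph of an array
#'
#' Either the built-in structural (catheter) adjacency, or a metric graph
#' linking every electrode pair within a given distance.
#'
#' @param array An `electrode_array`.
#' @param mode `"structural"` or `"metric"`.
#' @param radius_mm Linking radius for metric mode (mm, > 0).
#' @return Named list mapping electrode_id to character vector of neighbors.
#' @export
neighbor_graph <- function(array, mode = c("structural", "metric"),
                           radius_mm = NULL) {
  mode <- match.arg(mode)
  if (mode == "structural") return(array$adjacency)
  if (is.null(radius_mm) || !is.finite(radius_mm) || radius_mm <= 0) {
    abort("metric mode requires radius_mm > 0", class = "focalroi_error_geometry")
  }
  pos <- electrode_positions(array)
  d <- as.matrix(stats::dist(pos))
  ids <- rownames(pos)
  adj <- lapply(seq_along(ids), function(i) {
    ids[d[i, ] <= radius_mm & seq_along(ids) != i]
  })
  names(adj) <- ids
  adj
}

#' Spatial correlation of two sites
#'
#' Two sites correlate when their center-to-center Euclidean distance is
#' strictly less than the threshold (default 10 mm, the 1 cm rule).
#'
#' @param a,b 3-vectors (mm).
#' @param threshold_mm Correlation threshold (mm), strict.
#' @return A list with `correlated` (logical) and `distance_mm`.
#' @export
correlate_sites <- function(a, b, threshold_mm = 10) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3 || length(b) != 3 || !all(is.finite(c(a, b)))) {
    abort("sites must be finite 3-vectors", class = "focalroi_error_geometry")
  }
  d <- sqrt(sum((a - b)^2))
  list(correlated = d < threshold_mm, distance_mm = d)
}

# pairwise Euclidean distances between rows of two matrices (mm)
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  out <- outer(seq_len(nrow(a)), seq_len(nrow(b)),
               Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
  out
}

#' Serialize / deserialize an electrode array
#'
#' JSON layout: `{array_kind, electrodes:[{id, spline, index, xyz}],
#' adjacency:[[id,id],...]}` with edges listed once in sorted order.
#'
#' @param array An `electrode_array`.
#' @return `array_to_list()` returns a plain list; `array_from_list()`
#'   rebuilds the `electrode_array`.
#' @export
array_to_list <- function(array) {
  e <- array$electrodes
  edges <- list()
  for (id in names(array$adjacency)) {
    for (nb in array$adjacency[[id]]) {
      if (id < nb) edges[[length(edges) + 1]] <- c(id, nb)
    }
  }
  list(
    array_kind = array$array_kind,
    electrodes = lapply(seq_len(nrow(e)), function(i) {
      list(id = e$electrode_id[i], spline = e$spline[i], index = e$index[i],
           xyz = c(e$x[i], e$y[i], e$z[i]))
    }),
    adjacency = edges
  )
}

#' @rdname array_to_list
#' @param x A list as produced by `array_to_list()`.
#' @export
array_from_list <- function(x) {
  electrodes <- dplyr::bind_rows(lapply(x$electrodes, function(el) {
    xyz <- as.numeric(unlist(el$xyz))
    tibble(electrode_id = el$id, spline = as.integer(el$spline),
           index = as.integer(el$index),
           x = xyz[1], y = xyz[2], z = xyz[3])
  }))
  adjacency <- setNames(vector("list", nrow(electrodes)),
                        electrodes$electrode_id)
  adjacency <- lapply(adjacency, function(v) character())
  for (edge in x$adjacency) {
    edge <- as.character(unlist(edge))
    adjacency[[edge[1]]] <- c(adjacency[[edge[1]]], edge[2])
    adjacency[[edge[2]]] <- c(adjacency[[edge[2]]], edge[1])
  }
  electrode_array(electrodes, adjacency, x$array_kind)
}
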