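#' Atrial surface stand-in
#'
#' A closed convex surface (ellipsoid, mm semi-axes) on which simulated
#' sources live and electrodes are placed. The default is a sphere of radius
#' 28.8 mm whose circular cross-section (26.0 cm^2) matches a typical
#' planimetered left-atrial area. Geodesic distances are only defined for
#' spherical surfaces (great-circle arcs); the simulator uses a sphere.
#'
#' @param semi_axes Positive 3-vector of semi-axes (mm); equal values give a
#'   sphere.
#' @param center 3-vector, surface center (mm).
#' @return An object of class `atrial_surface`.
#' @export
atrial_surface <- function(semi_axes = c(28.8, 28.8, 28.8), center = c(0, 0, 0)) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || !all(is.finite(semi_axes)) || any(semi_axes <= 0)) {
    abort("semi_axes must be three positive numbers",
          class = "focalroi_error_geometry")
  }
  structure(list(semi_axes = semi_axes, center = as.numeric(center)),
            class = "atrial_surface")
}

is_sphere <- function(surface) {
  diff(range(surface$semi_axes)) < 1e-9
}

#' @export
print.atrial_surface <- function(x, ...) {
  cat(sprintf("<atrial_surface: semi-axes %s mm, area %.1f cm^2>\n",
              paste(signif(x$semi_axes, 3), collapse = "/"),
              surface_area(x)))
  invisible(x)
}

#' Surface area of an atrial surface
#'
#' Exact for spheres; Thomsen's approximation (p = 1.6075, relative error
#' below 1.1\%) for general ellipsoids.
#'
#' @param surface An `atrial_surface`.
#' @return Area in cm^2.
#' @export
surface_area <- function(surface) {
  ax <- surface$semi_axes
  if (is_sphere(surface)) {
    a_mm2 <- 4 * pi * ax[1]^2
  } else {
    p <- 1.6075
    a <- ax[1]; b <- ax[2]; c <- ax[3]
    a_mm2 <- 4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
  }
  a_mm2 / 100
}

#' Project points onto the surface
#'
#' Radial (center-directed) projection; for a sphere this is the nearest
#' surface point. Projected points satisfy the surface equation exactly.
#'
#' @param surface An `atrial_surface`.
#' @param points n x 3 matrix or 3-vector (mm).
#' @return Matrix of projected points (n x 3).
#' @export
project_to_surface <- function(surface, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  rel <- sweep(p, 2, surface$center)
  scaled <- sweep(rel, 2, surface$semi_axes, "/")
  r <- sqrt(rowSums(scaled^2))
  if (any(r < 1e-12)) {
    abort("cannot project the surface center", class = "focalroi_error_geometry")
  }
  sweep(sweep(rel, 1, r, "/"), 2, surface$center, "+")
}

#' Geodesic distance on a spherical surface
#'
#' Great-circle distance between points (projected onto the sphere first).
#'
#' @param surface A spherical `atrial_surface`.
#' @param from 3-vector (mm).
#' @param to n x 3 matrix or 3-vector (mm).
#' @return Numeric vector of distances (mm).
#' @export
geodesic_distance <- function(surface, from, to) {
  if (!is_sphere(surface)) {
    abort("geodesic_distance is only defined for spherical surfaces",
          class = "focalroi_error_geometry")
  }
  r <- surface$semi_axes[1]
  a <- project_to_surface(surface, from) - matrix(surface$center, 1)
  b <- sweep(project_to_surface(surface, to), 2, surface$center)
  cosang <- (b %*% t(a))[, 1] / (r * r)
  r * acos(pmin(1, pmax(-1, cosang)))
}
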