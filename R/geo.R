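# Geodesic primitives: great-circle distances on a spherical earth and the
# small-offset conversion between metric east/north displacements and
# latitude/longitude increments used to place tiles and waypoints.

#' Mean-earth sphere model
#'
#' @param radius_m Sphere radius in meters. Default is the mean earth radius,
#'   6,371,000 m.
#' @return An `earth_model` object.
#' @export
earth_model <- function(radius_m = 6371000) {
  stopifnot_finite(radius_m, "earth radius")
  if (radius_m <= 0) abort_input("earth radius must be > 0")
  structure(list(radius_m = radius_m), class = "earth_model")
}

#' Geographic point (WGS-84 latitude/longitude, degrees)
#'
#' @param lat Latitude in degrees, in \[-90, 90\].
#' @param lon Longitude in degrees, in \[-180, 180).
#' @return A `geo_point` object with fields `lat` and `lon`.
#' @export
geo_point <- function(lat, lon) {
  stopifnot_finite(lat, "latitude")
  stopifnot_finite(lon, "longitude")
  if (lat < -90 || lat > 90) abort_input("latitude outside [-90, 90]")
  if (lon < -180 || lon >= 180) abort_input("longitude outside [-180, 180)")
  structure(list(lat = lat, lon = lon), class = "geo_point")
}

#' @export
format.geo_point <- function(x, ...) sprintf("(%.7f, %.7f)", x$lat, x$lon)

#' @export
print.geo_point <- function(x, ...) {
  cat("geo_point", format(x), "\n")
  invisible(x)
}

#' Great-circle distance between two points (haversine)
#'
#' Spherical great-circle distance
#' \deqn{d = 2R \arcsin\sqrt{\sin^2\frac{\Delta\varphi}{2} +
#'   \cos\varphi_1\cos\varphi_2\sin^2\frac{\Delta\lambda}{2}}}
#' with latitudes/longitudes in radians and `R` the sphere radius.
#'
#' @param p1,p2 `geo_point`s.
#' @param earth An [earth_model()].
#' @return Distance in meters (non-negative, at most `pi * R`).
#' @export
haversine_distance <- function(p1, p2, earth = earth_model()) {
  phi1 <- p1$lat * pi / 180; phi2 <- p2$lat * pi / 180
  lam1 <- p1$lon * pi / 180; lam2 <- p2$lon * pi / 180
  a <- sin((phi2 - phi1) / 2)^2 +
    cos(phi1) * cos(phi2) * sin((lam2 - lam1) / 2)^2
  # guard rounding: a must stay in [0, 1] for asin
  2 * earth$radius_m * asin(sqrt(pmin(pmax(a, 0), 1)))
}

#' Convert a metric east/north offset to lat/lon increments
#'
#' Small-offset (flat-earth) conversion: a northward displacement `dy` maps to
#' a latitude increment `dlat = (180 / (pi R)) * dy`. For longitude the
#' `"literal"` mode applies the same factor to `dx` (exact only at the
#' equator); the default `"corrected"` mode divides additionally by
#' `cos(lat)` so east-west spacing is preserved at any latitude. Valid for
#' offsets small relative to the earth radius (intended for |offset| <= 50 km).
#'
#' @param dx,dy Offset in meters east (`dx`) and north (`dy`).
#' @param ref Reference `geo_point` (its latitude enters the corrected mode).
#' @param earth An [earth_model()].
#' @param mode `"corrected"` (default) or `"literal"`.
#' @return Named numeric `c(dlat=, dlon=)` in degrees.
#' @export
offset_to_increment <- function(dx, dy, ref, earth = earth_model(),
                                mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  stopifnot_finite(dx, "dx"); stopifnot_finite(dy, "dy")
  k <- 180 / (pi * earth$radius_m)
  dlat <- k * dy
  dlon <- k * dx
  if (mode == "corrected") {
    if (abs(ref$lat) >= 89.9)
      abort_input("corrected mode undefined near the poles (|lat| >= 89.9)",
                  class = "agrisurvey_polar_region")
    dlon <- dlon / cos(ref$lat * pi / 180)
  }
  c(dlat = dlat, dlon = dlon)
}

#' Advance a point by a metric offset
#'
#' Applies [offset_to_increment()] and returns the displaced point. The
#' conversion is intended to be applied accumulatively along a route; the
#' increments are linear in the offset, so many small steps equal one large
#' step of the same total displacement.
#'
#' @inheritParams offset_to_increment
#' @param p Starting `geo_point`.
#' @return A `geo_point`.
#' @export
advance_point <- function(p, dx, dy, earth = earth_model(),
                          mode = c("corrected", "literal")) {
  inc <- offset_to_increment(dx, dy, p, earth, mode)
  geo_point(p$lat + inc[["dlat"]], p$lon + inc[["dlon"]])
}

# Inverse of offset_to_increment: metric east/north coordinates of `p`
# relative to `ref` in the local tangent plane. Used to bring polygon
# vertices into the tessellation plane.
local_xy <- function(p, ref, earth = earth_model(),
                     mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  k <- pi * earth$radius_m / 180
  y <- (p$lat - ref$lat) * k
  x <- (p$lon - ref$lon) * k
  if (mode == "corrected") {
    if (abs(ref$lat) >= 89.9)
      abort_input("corrected mode undefined near the poles (|lat| >= 89.9)",
                  class = "agrisurvey_polar_region")
    x <- x * cos(ref$lat * pi / 180)
  }
  c(x = x, y = y)
}
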