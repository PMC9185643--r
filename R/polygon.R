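# Survey polygons and the planar point-in-polygon test used by tessellation.

#' Survey polygon over a field area
#'
#' An ordered ring of WGS-84 vertices (implicitly closed; a repeated closing
#' vertex is dropped). The ring must have at least 3 vertices, no duplicate
#' consecutive vertices, and must not self-intersect.
#'
#' @param lat,lon Numeric vectors of vertex coordinates, degrees.
#' @param name,description Free-text mission metadata.
#' @return A `survey_polygon` object.
#' @export
survey_polygon <- function(lat, lon, name = "field", description = "") {
  stopifnot_finite(lat, "lat"); stopifnot_finite(lon, "lon")
  if (length(lat) != length(lon)) abort_input("lat/lon length mismatch")
  n <- length(lat)
  if (n >= 4 && lat[1] == lat[n] && lon[1] == lon[n]) {
    lat <- lat[-n]; lon <- lon[-n]; n <- n - 1
  }
  if (n < 3) abort_input("polygon needs at least 3 distinct vertices")
  dup <- which(lat == c(lat[-1], lat[1]) & lon == c(lon[-1], lon[1]))
  if (length(dup)) abort_input("duplicate consecutive vertices in polygon")
  poly <- structure(list(lat = lat, lon = lon, name = name,
                         description = description),
                    class = "survey_polygon")
  xy <- polygon_local_xy(poly)
  if (ring_self_intersects(xy$x, xy$y))
    abort_input("polygon is self-intersecting")
  if (abs(ring_area(xy$x, xy$y)) < 1e-9)
    abort_input("degenerate polygon: zero area")
  poly
}

#' Read a survey polygon from a GeoJSON file
#'
#' Accepts a Polygon geometry, a Feature wrapping one, or a FeatureCollection
#' (first feature used). Only the exterior ring is used; polygons with holes
#' are rejected. GeoJSON coordinate order is (lon, lat) per the standard.
#'
#' @param path GeoJSON file path.
#' @return A [survey_polygon()].
#' @export
read_polygon_geojson <- function(path) {
  if (!file.exists(path)) abort_input(paste0("GeoJSON not found: ", path))
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  name <- "field"; descr <- ""
  if (identical(g$type, "FeatureCollection")) {
    if (!length(g$features)) abort_input("empty FeatureCollection")
    g <- g$features[[1]]
  }
  if (identical(g$type, "Feature")) {
    name <- g$properties$name %||% name
    descr <- g$properties$description %||% descr
    g <- g$geometry
  }
  if (!identical(g$type, "Polygon"))
    abort_input(paste0("expected a Polygon geometry, got: ", g$type %||% "?"))
  rings <- g$coordinates
  if (length(rings) > 1)
    abort_input("polygons with interior rings (holes) are not supported")
  ring <- rings[[1]]
  lon <- vapply(ring, function(v) as.numeric(v[[1]]), 0)
  lat <- vapply(ring, function(v) as.numeric(v[[2]]), 0)
  survey_polygon(lat, lon, name = name, description = descr)
}

# Vertices in the local metric plane anchored at the bounding-box
# bottom-left corner (the tessellation reference point).
polygon_local_xy <- function(poly, earth = earth_model(),
                             mode = "corrected") {
  ref <- geo_point(min(poly$lat), min(poly$lon))
  n <- length(poly$lat)
  xy <- vapply(seq_len(n), function(i)
    local_xy(geo_point(poly$lat[i], poly$lon[i]), ref, earth, mode),
    c(x = 0, y = 0))
  # snap to the micrometer: the degrees->meters round trip carries ~1e-8 m
  # of floating noise which would otherwise flip the half-open boundary rule
  list(x = round(xy["x", ], 6), y = round(xy["y", ], 6), ref = ref)
}

ring_area <- function(x, y) {
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

seg_intersect_proper <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- cross(cx, cy, dx, dy, ax, ay)
  d2 <- cross(cx, cy, dx, dy, bx, by)
  d3 <- cross(ax, ay, bx, by, cx, cy)
  d4 <- cross(ax, ay, bx, by, dx, dy)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(x, y) {
  n <- length(x)
  nxt <- c(seq_len(n)[-1], 1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (seg_intersect_proper(x[i], y[i], x[nxt[i]], y[nxt[i]],
                               x[j], y[j], x[nxt[j]], y[nxt[j]]))
        return(TRUE)
    }
  }
  FALSE
}

#' Ray-casting point-in-polygon test
#'
#' Casts a horizontal ray from each point and counts edge crossings: an odd
#' count means inside. Edges are treated half-open (lower-inclusive), so every
#' boundary point is classified deterministically and adjacent tiles never
#' both claim a shared edge point.
#'
#' @param px,py Numeric vectors of planar point coordinates (meters).
#' @param ring_x,ring_y Polygon ring vertex coordinates in the same plane.
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, ring_x, ring_y) {
  n <- length(ring_x)
  if (n < 3) abort_input("ring needs at least 3 vertices")
  if (abs(ring_area(ring_x, ring_y)) == 0)
    abort_input("degenerate ring: zero area")
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring_x[i]; yi <- ring_y[i]
    xj <- ring_x[j]; yj <- ring_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
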