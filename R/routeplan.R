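# Route planning: tessellate the survey polygon with camera footprints,
# order the kept tiles in a boustrophedon zigzag, build the waypoint route,
# and split it into battery-safe sub-routes with go-home waypoints.

#' Tile inclusion rule
#'
#' A tile is kept when its center or at least one of its four corners lies
#' inside the polygon. Keeping corner-only tiles avoids an incomplete
#' tessellation at the polygon boundary.
#'
#' @param cx,cy Tile center, local plane meters.
#' @param half_x,half_y Footprint half-sizes, meters.
#' @param ring_x,ring_y Polygon ring in the same plane.
#' @return `TRUE` if the tile is kept.
#' @export
keep_tile <- function(cx, cy, half_x, half_y, ring_x, ring_y) {
  px <- c(cx, cx - half_x, cx + half_x, cx - half_x, cx + half_x)
  py <- c(cy, cy - half_y, cy - half_y, cy + half_y, cy + half_y)
  any(point_in_polygon(px, py, ring_x, ring_y))
}

#' Tessellate a survey polygon with camera footprint tiles
#'
#' Lays a grid of footprint-sized tiles over the polygon's bounding box,
#' anchored so the first tile's bottom-left corner sits at the bounding box's
#' bottom-left corner (the local reference point), advancing by the step
#' distances. Tiles passing [keep_tile()] are returned in deterministic
#' column-major `(i, j)` order, with centers both in the local plane and as
#' geographic points.
#'
#' @param poly A [survey_polygon()].
#' @param fp A [ground_footprint()].
#' @param step Named numeric `c(dx=, dy=)` from [step_distances()];
#'   defaults to the footprint (no overlap).
#' @param earth An [earth_model()].
#' @param mode Offset conversion mode, `"corrected"` (default) or `"literal"`.
#' @return A data frame of tiles: `i`, `j`, `x`, `y`, `lat`, `lon`.
#' @export
tessellate <- function(poly, fp, step = NULL, earth = earth_model(),
                       mode = "corrected") {
  if (is.null(step)) step <- c(dx = fp$d_fov_x, dy = fp$d_fov_y)
  if (step[["dx"]] > fp$d_fov_x + 1e-9 || step[["dy"]] > fp$d_fov_y + 1e-9)
    abort_input("step must not exceed the footprint (gaps in coverage)")
  loc <- polygon_local_xy(poly, earth, mode)
  xmax <- max(loc$x); ymax <- max(loc$y)
  hx <- fp$d_fov_x / 2; hy <- fp$d_fov_y / 2
  # candidate centers: first tile's lower-left corner at the reference point
  is <- 0:max(0, ceiling((xmax - hx) / step[["dx"]]))
  js <- 0:max(0, ceiling((ymax - hy) / step[["dy"]]))
  grid <- expand.grid(j = js, i = is)   # column-major: i slow, j fast
  grid <- grid[, c("i", "j")]
  grid$x <- hx + grid$i * step[["dx"]]
  grid$y <- hy + grid$j * step[["dy"]]
  keep <- vapply(seq_len(nrow(grid)), function(k)
    keep_tile(grid$x[k], grid$y[k], hx, hy, loc$x, loc$y), TRUE)
  tiles <- grid[keep, , drop = FALSE]
  if (!nrow(tiles))
    abort_input("polygon admits no tiles at this footprint (empty route)",
                class = "agrisurvey_empty_route")
  gp <- lapply(seq_len(nrow(tiles)), function(k)
    advance_point(loc$ref, tiles$x[k], tiles$y[k], earth, mode))
  tiles$lat <- vapply(gp, `[[`, 0, "lat")
  tiles$lon <- vapply(gp, `[[`, 0, "lon")
  rownames(tiles) <- NULL
  attr(tiles, "ref") <- loc$ref
  attr(tiles, "half") <- c(hx = hx, hy = hy)
  tiles
}

#' Order tiles in a boustrophedon zigzag
#'
#' Columns are visited left to right; the first visited column is flown
#' bottom to top, the next top to bottom, alternating. On a full rectangular
#' grid consecutive tiles then differ in exactly one grid coordinate
#' (Up, Right, Down, Right, ...), starting at the bottom-left-most kept tile.
#'
#' @param tiles Tile data frame from [tessellate()].
#' @return The same data frame, reordered.
#' @export
order_zigzag <- function(tiles) {
  if (!nrow(tiles)) return(tiles)
  cols <- sort(unique(tiles$i))
  out <- vector("list", length(cols))
  for (k in seq_along(cols)) {
    col <- tiles[tiles$i == cols[k], , drop = FALSE]
    col <- col[order(col$j), , drop = FALSE]
    if (k %% 2 == 0) col <- col[rev(seq_len(nrow(col))), , drop = FALSE]
    out[[k]] <- col
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attributes(res)[c("ref", "half")] <- attributes(tiles)[c("ref", "half")]
  res
}

initial_bearing <- function(p1, p2) {
  phi1 <- p1$lat * pi / 180; phi2 <- p2$lat * pi / 180
  dl <- (p2$lon - p1$lon) * pi / 180
  th <- atan2(sin(dl) * cos(phi2),
              cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl))
  (th * 180 / pi + 360) %% 360
}

#' Build a waypoint route from ordered tiles
#'
#' One survey waypoint per tile center, at constant altitude and per-waypoint
#' wait time. Heading is the bearing of the incoming leg (0 for the first
#' waypoint).
#'
#' @param tiles Ordered tile data frame from [order_zigzag()].
#' @param altitude_m Flight altitude AGL, meters (from [flight_height()]).
#' @param wait_s Hover time at each waypoint, seconds.
#' @param home Launch/return `geo_point`; defaults to the first waypoint.
#' @param metadata Named list of mission metadata (gsd, overlap, camera...).
#' @return A `route_plan` object.
#' @export
build_route <- function(tiles, altitude_m, wait_s = 0, home = NULL,
                        metadata = list()) {
  if (!nrow(tiles))
    abort_input("no tiles to route (empty route)",
                class = "agrisurvey_empty_route")
  if (altitude_m <= 0) abort_input("altitude must be > 0")
  if (wait_s < 0) abort_input("wait time must be >= 0")
  n <- nrow(tiles)
  heading <- numeric(n)
  for (k in seq_len(n)[-1])
    heading[k] <- initial_bearing(geo_point(tiles$lat[k - 1], tiles$lon[k - 1]),
                                  geo_point(tiles$lat[k], tiles$lon[k]))
  wp <- data.frame(lat = tiles$lat, lon = tiles$lon,
                   alt_m = altitude_m, wait_s = wait_s,
                   heading_deg = heading, kind = "survey",
                   stringsAsFactors = FALSE)
  if (is.null(home)) home <- geo_point(wp$lat[1], wp$lon[1])
  route_plan(wp, home, metadata)
}

#' Route plan constructor
#'
#' @param waypoints Data frame with columns `lat`, `lon`, `alt_m`, `wait_s`,
#'   `heading_deg`, `kind` (`"survey"` or `"go_home"`).
#' @param home Launch/return `geo_point`.
#' @param metadata Named list of mission metadata.
#' @return A `route_plan` object.
#' @export
route_plan <- function(waypoints, home, metadata = list()) {
  if (!nrow(waypoints)) abort_input("route needs at least one waypoint",
                                    class = "agrisurvey_empty_route")
  if (any(waypoints$alt_m <= 0)) abort_input("altitudes must be > 0")
  if (any(waypoints$wait_s < 0)) abort_input("wait times must be >= 0")
  gh <- waypoints$kind == "go_home"
  if (any(gh) && (any(waypoints$lat[gh] != home$lat) ||
                  any(waypoints$lon[gh] != home$lon)))
    abort_input("go_home waypoints must be located at home")
  structure(list(waypoints = waypoints, home = home, metadata = metadata),
            class = "route_plan")
}

#' @export
print.route_plan <- function(x, ...) {
  n_gh <- sum(x$waypoints$kind == "go_home")
  cat(sprintf("route_plan: %d waypoints (%d go-home), home %s, alt %.1f m\n",
              nrow(x$waypoints), n_gh, format(x$home),
              x$waypoints$alt_m[1]))
  invisible(x)
}

#' Split a route into battery-safe sub-routes
#'
#' Scans the waypoints in order. At waypoint `w_i` the flight risk of the next
#' leg is `d(w_i, w_{i+1}) + d(w_{i+1}, home)`: the distance to reach the next
#' waypoint plus the straight-line return home from there. When the risk
#' exceeds `d_max` a go-home waypoint is inserted after `w_i`, starting a new
#' sub-route from home. Ground (2-D) distances are used.
#'
#' @param route A `route_plan`.
#' @param d_max Maximum allowed leg + return-home distance, meters. A default
#'   can be derived from endurance and cruise speed, see [default_d_max()].
#' @param earth An [earth_model()].
#' @return A new `route_plan` with go-home waypoints inserted.
#' @export
insert_gohome <- function(route, d_max, earth = earth_model()) {
  wp <- route$waypoints
  home <- route$home
  if (d_max <= 0) abort_input("d_max must be > 0")
  pts <- lapply(seq_len(nrow(wp)), function(k) geo_point(wp$lat[k], wp$lon[k]))
  d_home <- vapply(pts, haversine_distance, 0, p2 = home, earth = earth)
  bad <- which(2 * d_home > d_max)
  if (length(bad))
    abort_input(sprintf(
      "waypoint %d unreachable: 2 x d(home, w) = %.1f m exceeds d_max = %.1f m",
      bad[1], 2 * d_home[bad[1]], d_max),
      class = "agrisurvey_unreachable_waypoint")
  out <- wp[1, , drop = FALSE]
  pos <- pts[[1]]
  for (k in seq_len(nrow(wp))[-1]) {
    risk <- haversine_distance(pos, pts[[k]], earth) + d_home[k]
    row <- wp[k, , drop = FALSE]
    if (risk > d_max) {
      gh <- out[1, , drop = FALSE]
      gh$lat <- home$lat; gh$lon <- home$lon
      gh$alt_m <- wp$alt_m[k]; gh$wait_s <- 0
      gh$heading_deg <- initial_bearing(pos, home)
      gh$kind <- "go_home"
      out <- rbind(out, gh)
      pos <- home
      # the leg to the next waypoint is now flown from home
      row$heading_deg <- initial_bearing(pos, pts[[k]])
    }
    out <- rbind(out, row)
    pos <- pts[[k]]
  }
  rownames(out) <- NULL
  route_plan(out, home, route$metadata)
}

#' Default battery-safety distance
#'
#' Typical multirotor endurance is 20 to 30 minutes; the default risk budget
#' is endurance times cruise speed.
#'
#' @param endurance_min Usable flight endurance, minutes (default 20).
#' @param cruise_speed_ms Cruise speed, m/s (default 5).
#' @return Distance budget `d_max` in meters.
#' @export
default_d_max <- function(endurance_min = 20, cruise_speed_ms = 5) {
  endurance_min * 60 * cruise_speed_ms
}

#' Plan a complete survey mission
#'
#' Convenience wrapper: altitude from the target GSD, footprint at that
#' altitude, tessellation, zigzag ordering, route building, and optional
#' go-home splitting.
#'
#' @param poly A [survey_polygon()].
#' @param cam A [camera_model()].
#' @param gsd_m Target ground sampling distance, m/pixel.
#' @param overlap An [overlap_spec()].
#' @param wait_s Hover time per waypoint, seconds.
#' @param home Launch point; defaults to the first waypoint.
#' @param d_max Battery-safety distance, meters, or `NULL` to skip splitting.
#' @param earth An [earth_model()].
#' @param mode Offset conversion mode.
#' @return A `route_plan`.
#' @export
plan_mission <- function(poly, cam, gsd_m, overlap = overlap_spec(),
                         wait_s = 0, home = NULL, d_max = NULL,
                         earth = earth_model(), mode = "corrected") {
  alt <- flight_height(gsd_m, cam)
  fp <- ground_footprint(alt, cam)
  step <- step_distances(fp, overlap)
  tiles <- order_zigzag(tessellate(poly, fp, step, earth, mode))
  meta <- list(gsd_m = gsd_m, overlap_x = overlap$ox, overlap_y = overlap$oy,
               camera = cam$name, polygon = poly$name)
  route <- build_route(tiles, alt, wait_s, home, meta)
  if (!is.null(d_max)) route <- insert_gohome(route, d_max, earth)
  route
}
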