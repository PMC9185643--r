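# Independent oracles used across the suite. These deliberately reimplement
# the checked operations by a different method (winding number instead of
# ray crossing, exhaustive enumeration instead of the production grid walk,
# geosphere distances instead of the package's haversine) so agreement is
# informative.

# Winding-number point-in-polygon: sum of signed angles subtended by the
# edges; |total| > pi means inside. Undefined exactly on the boundary.
winding_inside <- function(px, py, ring_x, ring_y) {
  n <- length(ring_x)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a1 <- atan2(ring_y[i] - py, ring_x[i] - px)
    a2 <- atan2(ring_y[j] - py, ring_x[j] - px)
    da <- a2 - a1
    if (da > pi) da <- da - 2 * pi
    if (da <= -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi
}

# Distance from a point to a polygon boundary (to exclude near-boundary
# points from oracle comparisons).
dist_to_ring <- function(px, py, ring_x, ring_y) {
  n <- length(ring_x)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    vx <- ring_x[j] - ring_x[i]; vy <- ring_y[j] - ring_y[i]
    t <- ((px - ring_x[i]) * vx + (py - ring_y[i]) * vy) / (vx^2 + vy^2)
    t <- min(max(t, 0), 1)
    d <- sqrt((px - ring_x[i] - t * vx)^2 + (py - ring_y[i] - t * vy)^2)
    dmin <- min(dmin, d)
  }
  dmin
}

# Random simple (star-shaped, generally concave) polygon around the origin.
random_star_polygon <- function(n_vert, r_mean = 50) {
  ang <- sort(stats::runif(n_vert, 0, 2 * pi))
  rad <- stats::runif(n_vert, 0.3 * r_mean, r_mean)
  list(x = rad * cos(ang), y = rad * sin(ang))
}

# Brute-force tessellation count: exhaustively enumerate a padded candidate
# grid and apply the center-or-corner inclusion rule with an independent
# loop structure.
brute_force_tile_count <- function(ring_x, ring_y, fp_x, fp_y,
                                   step_x = fp_x, step_y = fp_y) {
  xmax <- max(ring_x); ymax <- max(ring_y)
  count <- 0
  kept <- list()
  for (i in 0:ceiling((xmax + fp_x) / step_x)) {
    for (j in 0:ceiling((ymax + fp_y) / step_y)) {
      cx <- fp_x / 2 + i * step_x
      cy <- fp_y / 2 + j * step_y
      tx <- c(cx, cx - fp_x / 2, cx + fp_x / 2, cx - fp_x / 2, cx + fp_x / 2)
      ty <- c(cy, cy - fp_y / 2, cy - fp_y / 2, cy + fp_y / 2, cy + fp_y / 2)
      inside <- mapply(function(a, b)
        agrisurvey::point_in_polygon(a, b, ring_x, ring_y), tx, ty)
      if (any(inside)) {
        count <- count + 1
        kept[[length(kept) + 1]] <- c(i = i, j = j)
      }
    }
  }
  list(count = count, ij = do.call(rbind, kept))
}

# Linear-scan go-home oracle: independent rescan of a waypoint table using
# geosphere great-circle distances, returning the survey-waypoint indices
# after which a go-home must be inserted.
gohome_positions_oracle <- function(wp, home, d_max) {
  gd <- function(p, q) geosphere::distHaversine(
    c(p[2], p[1]), c(q[2], q[1]), r = 6371000)
  h <- c(home$lat, home$lon)
  pos <- c(wp$lat[1], wp$lon[1])
  inserted <- integer()
  for (k in seq_len(nrow(wp))[-1]) {
    nxt <- c(wp$lat[k], wp$lon[k])
    risk <- gd(pos, nxt) + gd(nxt, h)
    if (risk > d_max) {
      inserted <- c(inserted, k - 1L)
      pos <- h
    }
    pos <- c(wp$lat[k], wp$lon[k])
  }
  inserted
}

# Direct scalar evaluation of each closed-form index on one spectrum,
# written out independently of the registry. `s` is a named vector keyed by
# wavelength, e.g. s[["860"]].
scalar_index_oracle <- function(name, s) {
  v <- function(nm) s[[as.character(nm)]]
  switch(name,
    NDVI = (v(860) - v(640)) / (v(860) + v(640)),
    RVI = v(860) / v(640),
    EVI = 2.5 * (v(860) - v(640)) / (v(860) + 6 * v(640) - 7.5 * v(450) + 1),
    SAVI = 1.5 * (v(860) - v(640)) / (v(860) + v(640) + 0.5),
    CCI = (v(531) - v(640)) / (v(531) + v(640)),
    ARVI = {
      rb <- 2 * v(640) - v(450)
      (v(860) - rb) / (v(860) + rb)
    },
    GCI = v(860) / v(560) - 1,
    MCARI = ((v(705) - v(680)) - 0.2 * (v(705) - v(560))) * v(705) / v(680),
    DCNI = (v(750) - v(705)) / (v(705) - v(680)) / (v(750) - v(680) + 0.03),
    SIPI = (v(800) - v(450)) / (v(800) - v(680)),
    NBR = (v(860) - v(2200)) / (v(860) + v(2200)),
    NDWI = (v(860) - v(1240)) / (v(860) + v(1240)),
    PRI = (v(531) - v(570)) / (v(531) + v(570)),
    PSRI = (v(680) - v(531)) / v(750),
    stop("no oracle for ", name))
}

# Constant-spectrum reflectance cube over the standard band set.
constant_cube <- function(s, rows = 4, cols = 5) {
  wl <- as.numeric(names(s))
  arr <- array(rep(unname(s), each = rows * cols),
               dim = c(rows, cols, length(s)))
  agrisurvey::hyper_cube(arr, wl, units = "reflectance")
}

standard_spectrum <- function(vals = NULL) {
  wl <- c(450, 531, 560, 570, 640, 680, 705, 750, 800, 860, 1240, 2200)
  if (is.null(vals)) vals <- stats::runif(length(wl), 0.02, 0.9)
  stats::setNames(as.list(vals), wl)
}

# Small survey route fixture: a straight line of waypoints `spacing_m` apart
# heading north from `home`.
line_route <- function(n, spacing_m = 100, start = agrisurvey::geo_point(40, -3.7),
                       alt = 50, wait = 0) {
  pts <- lapply(0:(n - 1), function(k)
    agrisurvey::advance_point(start, 0, k * spacing_m))
  wp <- data.frame(lat = vapply(pts, `[[`, 0, "lat"),
                   lon = vapply(pts, `[[`, 0, "lon"),
                   alt_m = alt, wait_s = wait, heading_deg = 0,
                   kind = "survey", stringsAsFactors = FALSE)
  agrisurvey::route_plan(wp, start)
}
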