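# Deterministic synthetic data: survey polygons and multispectral scenes
# with embedded calibration panels and vegetation regions of known NDVI,
# so every stage of the pipeline is testable without field data.

DEFAULT_WAVELENGTHS <- c(450, 531, 560, 570, 640, 680, 705, 750, 800, 860,
                         1240, 2200)

# A plausible dry-soil background spectrum over the default bands.
soil_spectrum <- function(wavelengths_nm) {
  0.08 + 0.12 * pmin(wavelengths_nm, 1400) / 1400
}

# Vegetation-like spectrum whose 640/860 nm bands are solved so that
# NDVI = (R860 - R640)/(R860 + R640) equals the target exactly, with
# red + NIR total fixed at 0.5.
vegetation_spectrum <- function(wavelengths_nm, ndvi_target, total = 0.5) {
  nir <- total * (1 + ndvi_target) / 2
  red <- total * (1 - ndvi_target) / 2
  s <- numeric(length(wavelengths_nm))
  for (k in seq_along(wavelengths_nm)) {
    w <- wavelengths_nm[k]
    s[k] <-
      if (abs(w - 640) < 1) red
      else if (abs(w - 860) < 1) nir
      else if (w < 500) 0.05
      else if (w < 600) 0.09
      else if (w < 690) red * 0.95
      else if (w < 730) (red + nir) / 2
      else if (w < 1000) nir * 0.95
      else if (w < 1500) 0.30
      else 0.12
  }
  s
}

#' Synthetic scene specification
#'
#' Describes a deterministic multispectral scene: image shape, band
#' wavelengths, gray-scale calibration panels (flat spectra), vegetation
#' regions with target NDVI values, the true linear sensor model
#' (`DN = (reflectance - offset) / gain + noise`), and the RNG seed.
#' Regions must be disjoint and in-bounds; NDVI targets must lie in
#' (-1, 1).
#'
#' @param rows,cols Image size in pixels.
#' @param wavelengths_nm Band centers, nm.
#' @param panels List of `list(label, reflectance, rows, cols)` rectangles.
#' @param regions List of `list(ndvi, rows, cols)` vegetation rectangles.
#' @param gain_true,offset_true Per-band true sensor gain (reflectance per
#'   DN) and offset (reflectance); scalars are recycled.
#' @param noise_sd Additive gaussian DN noise, DN units.
#' @param seed RNG seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(rows = 64, cols = 64,
                       wavelengths_nm = DEFAULT_WAVELENGTHS,
                       panels = NULL, regions = NULL,
                       gain_true = NULL, offset_true = 0.0,
                       noise_sd = 0, seed = 42) {
  nb <- length(wavelengths_nm)
  if (is.null(panels)) {
    refl <- panel_presets("mosaicmill")
    panels <- list(
      list(label = "black", reflectance = refl[["black"]],
           rows = c(1, 8), cols = c(1, 8)),
      list(label = "gray", reflectance = refl[["gray"]],
           rows = c(1, 8), cols = c(11, 18)),
      list(label = "white", reflectance = refl[["white"]],
           rows = c(1, 8), cols = c(21, 28)))
  }
  if (is.null(regions))
    regions <- list(
      list(ndvi = 0.60, rows = c(13, 40), cols = c(1, 32)),
      list(ndvi = 0.20, rows = c(41, 64), cols = c(1, 32)),
      list(ndvi = 0.45, rows = c(13, 64), cols = c(33, 64)))
  if (is.null(gain_true))
    gain_true <- seq(0.0008, 0.0012, length.out = nb)
  gain_true <- rep_len(gain_true, nb)
  offset_true <- rep_len(offset_true, nb)
  rects <- c(lapply(panels, function(p) c(p$rows, p$cols)),
             lapply(regions, function(r) c(r$rows, r$cols)))
  for (rc in rects)
    if (rc[1] < 1 || rc[2] > rows || rc[3] < 1 || rc[4] > cols)
      abort_input("panel/region rectangle outside image bounds")
  for (a in seq_along(rects)) for (b in seq_along(rects)) {
    if (b <= a) next
    ra <- rects[[a]]; rb <- rects[[b]]
    if (ra[1] <= rb[2] && rb[1] <= ra[2] && ra[3] <= rb[4] && rb[3] <= ra[4])
      abort_input("panel/region rectangles overlap")
  }
  for (r in regions)
    if (r$ndvi <= -1 || r$ndvi >= 1)
      abort_input("region NDVI target outside (-1, 1)")
  structure(list(rows = rows, cols = cols, wavelengths_nm = wavelengths_nm,
                 panels = panels, regions = regions, gain_true = gain_true,
                 offset_true = offset_true, noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

#' Generate a synthetic DN scene with ground truth
#'
#' Builds the reflectance field (soil background, vegetation regions whose
#' 640/860 nm reflectances satisfy their NDVI target exactly, flat-spectrum
#' panels), then inverts the true linear sensor model to digital numbers and
#' adds gaussian DN noise. Identical seeds give bit-identical scenes.
#'
#' @param spec A [scene_spec()].
#' @return List with `cube` (DN [hyper_cube()]), and `truth`: the noiseless
#'   reflectance array, per-band `gain`/`offset`, panel specs, region table,
#'   the constructed NDVI field and the healthy fraction (NDVI > 0.3).
#' @export
make_scene <- function(spec = scene_spec()) {
  wl <- spec$wavelengths_nm
  nb <- length(wl)
  refl <- array(rep(soil_spectrum(wl), each = spec$rows * spec$cols),
                dim = c(spec$rows, spec$cols, nb))
  for (r in spec$regions) {
    s <- vegetation_spectrum(wl, r$ndvi)
    for (b in seq_len(nb))
      refl[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2], b] <- s[b]
  }
  panel_specs <- lapply(spec$panels, function(p)
    panel_spec(p$label, p$reflectance, p$rows, p$cols))
  for (p in spec$panels) {
    pr <- rep_len(p$reflectance, nb)
    for (b in seq_len(nb))
      refl[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2], b] <- pr[b]
  }
  dn <- refl
  for (b in seq_len(nb))
    dn[, , b] <- (refl[, , b] - spec$offset_true[b]) / spec$gain_true[b]
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    dn <- dn + array(stats::rnorm(length(dn), sd = spec$noise_sd), dim(dn))
  }
  bi <- which.min(abs(wl - 860)); br <- which.min(abs(wl - 640))
  ndvi_true <- (refl[, , bi] - refl[, , br]) / (refl[, , bi] + refl[, , br])
  truth <- list(reflectance = refl, gain = spec$gain_true,
                offset = spec$offset_true, panels = panel_specs,
                regions = spec$regions, ndvi = ndvi_true,
                healthy_fraction = mean(ndvi_true > 0.3),
                wavelengths_nm = wl, noise_sd = spec$noise_sd,
                seed = spec$seed)
  list(cube = hyper_cube(dn, wl, units = "DN"), truth = truth)
}

#' Generate a deterministic survey polygon fixture
#'
#' `"rectangle"`: an axis-aligned `size_m[1]` (east) by `size_m[2]` (north)
#' rectangle. `"L"`: a 6-vertex non-convex L shape. `"concave12"`: a simple
#' concave 12-gon (alternating-radius star). Vertices are placed in WGS-84
#' around the anchor using the corrected metric-offset conversion.
#'
#' @param kind Shape name.
#' @param size_m Size in meters: `c(width, height)` for the rectangle,
#'   a scalar arm length / outer radius otherwise.
#' @param anchor `geo_point` at the shape's bottom-left (or center for
#'   `concave12`).
#' @return A [survey_polygon()].
#' @export
make_polygon <- function(kind = c("rectangle", "L", "concave12"),
                         size_m = c(100, 120),
                         anchor = geo_point(40.0, -3.7)) {
  kind <- match.arg(kind)
  if (any(size_m <= 0)) abort_input("size must be > 0")
  off <- switch(kind,
    rectangle = {
      w <- size_m[1]; h <- if (length(size_m) > 1) size_m[2] else size_m[1]
      list(c(0, 0), c(w, 0), c(w, h), c(0, h))
    },
    L = {
      a <- size_m[1]
      list(c(0, 0), c(a, 0), c(a, a / 2), c(a / 2, a / 2),
           c(a / 2, a), c(0, a))
    },
    concave12 = {
      r <- size_m[1]
      ang <- (0:11) * pi / 6
      rad <- rep(c(r, 0.45 * r), 6)
      lapply(seq_along(ang), function(k)
        c(rad[k] * cos(ang[k]), rad[k] * sin(ang[k])))
    })
  pts <- lapply(off, function(o) advance_point(anchor, o[1], o[2]))
  survey_polygon(vapply(pts, `[[`, 0, "lat"), vapply(pts, `[[`, 0, "lon"),
                 name = kind)
}
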