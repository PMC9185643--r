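# Camera/optics model: flight altitude for a target ground sampling distance,
# ground footprint of one frame, and the inter-tile step distances.

#' Pinhole camera model for nadir survey imaging
#'
#' Either `pixel_pitch_mm` or both `sensor_width_mm` and `sensor_height_mm`
#' must be given; the other pair is derived (`sensor_width = pitch * n_px_x`,
#' etc.). Half-angles of the field of view follow the pinhole relations
#' `tan(beta/2) = sensor_width / (2 focal_length)` (horizontal) and
#' `tan(alpha/2) = sensor_height / (2 focal_length)` (vertical).
#'
#' @param focal_length_mm Lens focal length, mm.
#' @param pixel_pitch_mm Pixel pitch, mm per pixel.
#' @param n_px_x,n_px_y Sensor resolution in pixels (across / along track).
#' @param sensor_width_mm,sensor_height_mm Alternative to `pixel_pitch_mm`.
#' @param name Optional camera name carried into mission metadata.
#' @return A `camera_model` object.
#' @export
camera_model <- function(focal_length_mm, pixel_pitch_mm = NULL,
                         n_px_x, n_px_y,
                         sensor_width_mm = NULL, sensor_height_mm = NULL,
                         name = "camera") {
  stopifnot_finite(focal_length_mm, "focal length")
  if (focal_length_mm <= 0) abort_input("focal length must be > 0")
  if (is.null(pixel_pitch_mm)) {
    if (is.null(sensor_width_mm) || is.null(sensor_height_mm))
      abort_input("give pixel_pitch_mm or sensor_width_mm + sensor_height_mm")
    px <- sensor_width_mm / n_px_x
    py <- sensor_height_mm / n_px_y
    if (abs(px - py) > 1e-9 * px)
      abort_input("non-square pixels not supported: width/height pitch differ")
    pixel_pitch_mm <- px
  }
  stopifnot_finite(pixel_pitch_mm, "pixel pitch")
  if (pixel_pitch_mm <= 0 || n_px_x <= 0 || n_px_y <= 0)
    abort_input("pixel pitch and resolution must be > 0")
  sw <- pixel_pitch_mm * n_px_x
  sh <- pixel_pitch_mm * n_px_y
  structure(list(
    name = name,
    focal_length_mm = focal_length_mm,
    pixel_pitch_mm = pixel_pitch_mm,
    n_px_x = as.integer(n_px_x), n_px_y = as.integer(n_px_y),
    sensor_width_mm = sw, sensor_height_mm = sh,
    beta = 2 * atan(sw / (2 * focal_length_mm)),   # horizontal FOV, rad
    alpha = 2 * atan(sh / (2 * focal_length_mm))   # vertical FOV, rad
  ), class = "camera_model")
}

#' Read a camera model from a YAML/JSON config file
#'
#' Keys: `focal_length_mm`, `n_px_x`, `n_px_y`, and either `pixel_pitch_mm`
#' or `sensor_width_mm` + `sensor_height_mm`; optional `name`.
#'
#' @param path Config file path.
#' @return A [camera_model()].
#' @export
read_camera_config <- function(path) {
  cfg <- read_config(path)
  camera_model(
    focal_length_mm = cfg$focal_length_mm,
    pixel_pitch_mm = cfg$pixel_pitch_mm,
    n_px_x = cfg$n_px_x, n_px_y = cfg$n_px_y,
    sensor_width_mm = cfg$sensor_width_mm,
    sensor_height_mm = cfg$sensor_height_mm,
    name = cfg$name %||% tools::file_path_sans_ext(basename(path))
  )
}

read_config <- function(path) {
  if (!file.exists(path)) abort_input(paste0("config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Flight altitude for a target ground sampling distance
#'
#' `H_f = GSD * focal_length / pixel_pitch`. With GSD in m/pixel and both
#' lens quantities in mm, the result is in meters.
#'
#' @param gsd_m Target ground sampling distance, meters per pixel.
#' @param cam A [camera_model()].
#' @return Flight height above ground, meters.
#' @export
flight_height <- function(gsd_m, cam) {
  stopifnot_finite(gsd_m, "gsd")
  if (gsd_m <= 0) abort_input("gsd must be > 0")
  gsd_m * cam$focal_length_mm / cam$pixel_pitch_mm
}

#' Ground footprint of one frame at a given altitude
#'
#' `d_fov_x = 2 h tan(beta/2)`, `d_fov_y = 2 h tan(alpha/2)`. At the altitude
#' returned by [flight_height()] this equals GSD times the pixel counts.
#'
#' @param h_m Flight height above ground, meters.
#' @param cam A [camera_model()].
#' @return A `footprint` object with `d_fov_x`, `d_fov_y` in meters.
#' @export
ground_footprint <- function(h_m, cam) {
  stopifnot_finite(h_m, "height")
  if (h_m <= 0) abort_input("height must be > 0")
  structure(list(d_fov_x = 2 * h_m * tan(cam$beta / 2),
                 d_fov_y = 2 * h_m * tan(cam$alpha / 2)),
            class = "footprint")
}

#' Overlap specification as step fractions
#'
#' `ox`, `oy` are the fraction of the footprint advanced between consecutive
#' tiles: 1 means adjacent tiles touch with no overlap, 0.2 means an 80%
#' overlap. The image overlap fraction along an axis is `1 - o`.
#'
#' @param ox,oy Step fractions in (0, 1].
#' @return An `overlap_spec` object.
#' @export
overlap_spec <- function(ox = 1, oy = 1) {
  stopifnot_finite(ox, "ox"); stopifnot_finite(oy, "oy")
  if (ox <= 0 || ox > 1 || oy <= 0 || oy > 1)
    abort_input("overlap step fractions must be in (0, 1]")
  structure(list(ox = ox, oy = oy), class = "overlap_spec")
}

#' Inter-tile step distances
#'
#' `dx = d_fov_x * ox`, `dy = d_fov_y * oy`: the displacement between centers
#' of consecutive tiles along each axis.
#'
#' @param fp A [ground_footprint()].
#' @param ov An [overlap_spec()].
#' @return Named numeric `c(dx=, dy=)`, meters.
#' @export
step_distances <- function(fp, ov = overlap_spec()) {
  c(dx = fp$d_fov_x * ov$ox, dy = fp$d_fov_y * ov$oy)
}
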