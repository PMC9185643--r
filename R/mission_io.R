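# Mission export/import: versioned mission JSON and QGC WPL 110 text
# (the plain-text waypoint format consumed by Mission Planner).

MAV_CMD_NAV_WAYPOINT <- 16L
MAV_CMD_RETURN_TO_LAUNCH <- 20L
MAV_FRAME_GLOBAL_RELATIVE_ALT <- 3L

#' Export a route plan to file
#'
#' Two dialects:
#' \describe{
#'   \item{json}{A versioned object `{schema, home, metadata, waypoints}`
#'     where `waypoints` is an array of records
#'     `{lat, lon, alt_m, wait_s, heading_deg, kind}`.}
#'   \item{wpl}{A `QGC WPL 110` text file: one `NAV_WAYPOINT` row per survey
#'     waypoint (param1 = wait seconds, param4 = heading) and a
#'     `RETURN_TO_LAUNCH` row per go-home waypoint. The home location is
#'     carried on the return rows; WPL files with no go-home row import with
#'     home defaulted to the first waypoint.}
#' }
#' Output is bit-stable given identical inputs.
#'
#' @param route A `route_plan`.
#' @param path Output file path.
#' @param format `"json"` or `"wpl"`; inferred from the extension if missing.
#' @return `path`, invisibly.
#' @export
export_route <- function(route, path, format = NULL) {
  format <- format %||% infer_mission_format(path)
  if (!nrow(route$waypoints)) abort_input("cannot export an empty route")
  switch(format,
    json = export_route_json(route, path),
    wpl = export_route_wpl(route, path),
    abort_input(paste0("unknown mission format: ", format))
  )
  invisible(path)
}

#' Import a route plan from file
#'
#' Inverse of [export_route()] on files it wrote. A `QGC WPL` header with a
#' version other than 110 triggers a warning and a best-effort parse.
#'
#' @param path Mission file path.
#' @param format `"json"` or `"wpl"`; inferred from the extension if missing.
#' @return A `route_plan`.
#' @export
import_route <- function(path, format = NULL) {
  format <- format %||% infer_mission_format(path)
  if (!file.exists(path)) abort_input(paste0("mission file not found: ", path))
  switch(format,
    json = import_route_json(path),
    wpl = import_route_wpl(path),
    abort_input(paste0("unknown mission format: ", format))
  )
}

infer_mission_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) "json"
  else if (ext %in% c("wpl", "waypoints", "txt")) "wpl"
  else abort_input(paste0("cannot infer mission format from: ", path))
}

export_route_json <- function(route, path) {
  obj <- list(
    schema = "agrisurvey-mission/1",
    home = list(lat = route$home$lat, lon = route$home$lon),
    metadata = route$metadata,
    waypoints = route$waypoints
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
}

import_route_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    abort_input(paste0("malformed mission JSON: ",
                                       conditionMessage(e)),
                                class = "agrisurvey_parse_error"))
  if (is.null(obj$waypoints) || is.null(obj$home))
    abort_input("mission JSON missing 'waypoints' or 'home'",
                class = "agrisurvey_parse_error")
  wp <- as.data.frame(obj$waypoints)
  for (col in c("lat", "lon", "alt_m", "wait_s", "heading_deg"))
    wp[[col]] <- as.numeric(wp[[col]])
  route_plan(wp[, c("lat", "lon", "alt_m", "wait_s", "heading_deg", "kind")],
             geo_point(as.numeric(obj$home$lat), as.numeric(obj$home$lon)),
             as.list(obj$metadata))
}

num17 <- function(x) sprintf("%.17g", x)

export_route_wpl <- function(route, path) {
  wp <- route$waypoints
  rows <- character(nrow(wp))
  for (k in seq_len(nrow(wp))) {
    is_gh <- wp$kind[k] == "go_home"
    cmd <- if (is_gh) MAV_CMD_RETURN_TO_LAUNCH else MAV_CMD_NAV_WAYPOINT
    rows[k] <- paste(
      k - 1L,                          # sequence
      if (k == 1L) 1L else 0L,         # current
      MAV_FRAME_GLOBAL_RELATIVE_ALT,   # frame
      cmd,
      num17(wp$wait_s[k]),             # param1: hold/delay (s)
      "0", "0",
      num17(wp$heading_deg[k]),        # param4: yaw
      num17(wp$lat[k]), num17(wp$lon[k]), num17(wp$alt_m[k]),
      1L,                              # autocontinue
      sep = "\t")
  }
  writeLines(c("QGC WPL 110", rows), path)
}

import_route_wpl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    abort_input("empty WPL file", class = "agrisurvey_parse_error")
  hdr <- lines[1]
  if (!grepl("^QGC WPL ", hdr))
    abort_input("line 1: missing 'QGC WPL' header",
                class = "agrisurvey_parse_error")
  ver <- sub("^QGC WPL\\s+", "", hdr)
  if (ver != "110")
    warning(sprintf("WPL version %s (expected 110); best-effort parse", ver),
            call. = FALSE)
  body <- lines[-1]
  if (!length(body))
    abort_input("WPL file has no waypoint rows",
                class = "agrisurvey_parse_error")
  n <- length(body)
  wp <- data.frame(lat = numeric(n), lon = numeric(n), alt_m = numeric(n),
                   wait_s = numeric(n), heading_deg = numeric(n),
                   kind = character(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(body[k]), "[\t ]+")[[1]]
    if (length(f) < 12)
      abort_input(sprintf("line %d: expected 12 fields, got %d",
                          k + 1L, length(f)),
                  class = "agrisurvey_parse_error")
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      abort_input(sprintf("line %d: non-numeric field", k + 1L),
                  class = "agrisurvey_parse_error")
    cmd <- as.integer(v[4])
    wp$wait_s[k] <- v[5]
    wp$heading_deg[k] <- v[8]
    wp$lat[k] <- v[9]; wp$lon[k] <- v[10]; wp$alt_m[k] <- v[11]
    wp$kind[k] <- if (cmd == MAV_CMD_RETURN_TO_LAUNCH) "go_home" else "survey"
  }
  gh <- which(wp$kind == "go_home")
  home <- if (length(gh)) geo_point(wp$lat[gh[1]], wp$lon[gh[1]])
          else geo_point(wp$lat[1], wp$lon[1])
  route_plan(wp, home)
}
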