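# Multiband cube data model and raster I/O with wavelength-addressed band
# lookup. ENVI (.hdr/.dat) is the primary format and round-trips exactly;
# multiband TIFF is supported with a JSON sidecar carrying wavelengths and
# the value scaling (TIFF samples are stored scaled to [0, 1]).

#' Multispectral/hyperspectral image cube
#'
#' A rows x cols x bands numeric array with per-band center wavelengths in
#' nanometers. Missing pixels are `NA` internally; `nodata` is the sentinel
#' written to / read from files. Bands are stored in ascending wavelength
#' order (reordered on construction if needed) so index arithmetic is
#' deterministic.
#'
#' @param data 3-D numeric array, `rows x cols x n_bands` (a matrix is
#'   treated as a single band).
#' @param wavelengths_nm Numeric vector of band-center wavelengths, nm,
#'   one per band, strictly increasing after sorting.
#' @param units `"DN"` (raw digital numbers) or `"reflectance"`.
#' @param nodata File sentinel for missing pixels.
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(data, wavelengths_nm, units = c("DN", "reflectance"),
                       nodata = -9999) {
  units <- match.arg(units)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) abort_input("cube data must be a 3-D array")
  nb <- dim(data)[3]
  if (length(wavelengths_nm) != nb)
    abort_input(sprintf("%d bands but %d wavelengths listed",
                        nb, length(wavelengths_nm)))
  stopifnot_finite(wavelengths_nm, "wavelengths")
  ord <- order(wavelengths_nm)
  if (any(diff(wavelengths_nm[ord]) <= 0))
    abort_input("wavelengths must be distinct")
  if (!identical(ord, seq_len(nb))) {
    data <- data[, , ord, drop = FALSE]
    wavelengths_nm <- wavelengths_nm[ord]
  }
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 units = units, nodata = nodata),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hyper_cube: %d x %d pixels, %d bands (%g-%g nm), units %s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$units))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' Nearest-wavelength band lookup
#'
#' Returns the index of the band whose center wavelength is nearest to the
#' target; ties break toward the lower wavelength. If the nearest band
#' deviates by more than the tolerance, a missing-band error names the
#' requested wavelength.
#'
#' @param cube A [hyper_cube()].
#' @param target_nm Requested wavelength, nm.
#' @param tolerance_nm Maximum acceptable deviation, nm (default 15, a
#'   typical multispectral band half-width).
#' @return Integer band index.
#' @export
band_at <- function(cube, target_nm, tolerance_nm = 15) {
  if (tolerance_nm < 0) abort_input("tolerance must be >= 0")
  dev <- abs(cube$wavelengths_nm - target_nm)
  k <- which.min(dev)   # ties: first = lower wavelength (ascending order)
  if (dev[k] > tolerance_nm)
    abort_input(sprintf(
      "no band within %g nm of %g nm (nearest: %g nm)",
      tolerance_nm, target_nm, cube$wavelengths_nm[k]),
      class = "agrisurvey_missing_band")
  k
}

#' Extract one band as a matrix
#' @param cube A [hyper_cube()].
#' @param b Band index.
#' @return Numeric matrix.
#' @export
cube_band <- function(cube, b)
  matrix(cube$data[, , b], nrow = dim(cube$data)[1], ncol = dim(cube$data)[2])

ENVI_DTYPES <- list(`1` = list(what = "integer", size = 1, signed = FALSE),
                    `2` = list(what = "integer", size = 2, signed = TRUE),
                    `3` = list(what = "integer", size = 4, signed = TRUE),
                    `4` = list(what = "double", size = 4, signed = TRUE),
                    `5` = list(what = "double", size = 8, signed = TRUE),
                    `12` = list(what = "integer", size = 2, signed = FALSE))

#' Write a cube to file
#'
#' Format `"envi"` writes a binary BSQ `.dat` plus a text `.hdr` (wavelengths
#' and the nodata value in the header); integer DN cubes are stored as int32
#' and round-trip bitwise, other data as float32 (`dtype = "float64"` for
#' exact storage). Format `"tiff"` writes a multiband TIFF plus a
#' `<path>.json` sidecar with wavelengths, units and the linear scaling
#' applied to fit samples into [0, 1].
#'
#' @param cube A [hyper_cube()].
#' @param path Output path (`.dat`/`.hdr` pair for ENVI, `.tif` for TIFF).
#' @param format `"envi"` or `"tiff"`; inferred from the extension if missing.
#' @param dtype ENVI storage type: `"auto"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = NULL, dtype = "auto") {
  format <- format %||% infer_cube_format(path)
  switch(format,
    envi = write_cube_envi(cube, path, dtype),
    tiff = write_cube_tiff(cube, path),
    abort_input(paste0("unknown cube format: ", format)))
  invisible(path)
}

#' Read a cube from file
#'
#' Reads an ENVI `.hdr`/`.dat` pair or a multiband TIFF with its JSON
#' sidecar. A file without wavelength metadata is an error unless
#' `wavelengths_nm` overrides them.
#'
#' @param path Cube path.
#' @param format `"envi"` or `"tiff"`; inferred from the extension if missing.
#' @param wavelengths_nm Optional override for missing wavelength metadata.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, format = NULL, wavelengths_nm = NULL) {
  format <- format %||% infer_cube_format(path)
  switch(format,
    envi = read_cube_envi(path, wavelengths_nm),
    tiff = read_cube_tiff(path, wavelengths_nm),
    abort_input(paste0("unknown cube format: ", format)))
}

infer_cube_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dat", "hdr", "bsq", "envi", "raw", "img")) "envi"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else abort_input(paste0("cannot infer cube format from: ", path))
}

envi_paths <- function(path) {
  ext <- tolower(tools::file_ext(path))
  base <- if (ext == "hdr") tools::file_path_sans_ext(path) else path
  dat <- if (ext == "hdr") {
    cands <- paste0(base, c(".dat", ".bsq", ".img", ".raw", ""))
    hit <- cands[file.exists(cands)]
    if (length(hit)) hit[1] else paste0(base, ".dat")
  } else path
  list(hdr = paste0(if (ext %in% c("dat", "bsq", "img", "raw"))
    tools::file_path_sans_ext(path) else base, ".hdr"), dat = dat)
}

write_cube_envi <- function(cube, path, dtype = "auto") {
  p <- envi_paths(path)
  d <- dim(cube$data)
  vals <- cube$data
  vals[is.na(vals)] <- cube$nodata
  integral <- all(vals == round(vals)) && max(abs(vals)) < 2^31 - 1
  if (dtype == "auto")
    dtype <- if (cube$units == "DN" && integral) "int32" else "float32"
  code <- switch(dtype, int32 = 3L, float32 = 4L, float64 = 5L,
                 abort_input(paste0("unsupported dtype: ", dtype)))
  spec <- ENVI_DTYPES[[as.character(code)]]
  # BSQ: band sequential; R arrays are column-major (row index fastest), ENVI
  # rasters are row-major within a band, so transpose each band on write.
  con <- file(p$dat, "wb")
  on.exit(close(con), add = TRUE)
  for (b in seq_len(d[3])) {
    v <- as.vector(t(vals[, , b]))
    if (spec$what == "integer") v <- as.integer(round(v))
    if (code == 4L) writeBin(v, con, size = 4, endian = "little")
    else writeBin(v, con, size = spec$size, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {agrisurvey cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", code),
    "interleave = bsq",
    "byte order = 0",
    sprintf("agrisurvey units = %s", cube$units),
    sprintf("data ignore value = %s", num17(cube$nodata)),
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(num17(cube$wavelengths_nm), collapse = ", "))
  )
  writeLines(hdr, p$hdr)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  # fold brace-delimited multi-line values
  txt <- gsub("\\{([^}]*)\\}", "{\\1}", txt)
  keyval <- list()
  # match "key = value" where value may be a {...} block spanning lines
  m <- gregexpr("(?m)^([^=\n]+)=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)
  starts <- m[[1]]
  if (starts[1] != -1) {
    for (k in seq_along(starts)) {
      piece <- substr(txt, starts[k], starts[k] + attr(m[[1]], "match.length")[k] - 1)
      key <- trimws(sub("=.*", "", piece))
      val <- trimws(sub("^[^=]+=\\s*", "", piece))
      keyval[[tolower(key)]] <- val
    }
  }
  keyval
}

envi_num_list <- function(v) {
  v <- gsub("[{}]", "", v)
  as.numeric(trimws(strsplit(v, ",")[[1]]))
}

read_cube_envi <- function(path, wavelengths_nm = NULL) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) abort_input(paste0("ENVI header not found: ", p$hdr))
  if (!file.exists(p$dat)) abort_input(paste0("ENVI data file not found: ", p$dat))
  h <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type")
  miss <- need[!need %in% names(h)]
  if (length(miss))
    abort_input(paste0("ENVI header missing: ", paste(miss, collapse = ", ")))
  cols <- as.integer(h$samples); rows <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  code <- as.character(as.integer(h[["data type"]]))
  interleave <- tolower(h$interleave %||% "bsq")
  if (interleave != "bsq")
    abort_input(paste0("only BSQ interleave supported, got: ", interleave))
  spec <- ENVI_DTYPES[[code]]
  if (is.null(spec))
    abort_input(paste0("unsupported ENVI data type: ", code))
  con <- file(p$dat, "rb")
  on.exit(close(con), add = TRUE)
  arr <- array(NA_real_, dim = c(rows, cols, nb))
  for (b in seq_len(nb)) {
    v <- readBin(con, spec$what, n = rows * cols, size = spec$size,
                 signed = spec$signed, endian = "little")
    if (length(v) < rows * cols)
      abort_input("ENVI data file truncated")
    arr[, , b] <- t(matrix(as.numeric(v), nrow = cols, ncol = rows))
  }
  wl <- wavelengths_nm %||% (if (!is.null(h[["wavelength"]]))
    envi_num_list(h[["wavelength"]]) else NULL)
  if (is.null(wl))
    abort_input(paste0("no wavelength metadata in ", p$hdr,
                       "; pass wavelengths_nm (CLI: --wavelengths)"))
  units <- h[["agrisurvey units"]] %||% "DN"
  nodata <- if (!is.null(h[["data ignore value"]]))
    as.numeric(h[["data ignore value"]]) else -9999
  arr[arr == nodata] <- NA_real_
  hyper_cube(arr, wl, units = units, nodata = nodata)
}

# TIFF samples must lie in [0, 1]; values are stored linearly rescaled with
# the scale/offset recorded in the JSON sidecar. Missing pixels are carried
# in an extra trailing mask plane (1 = valid) so the sentinel never enters
# the value scaling.
write_cube_tiff <- function(cube, path) {
  d <- dim(cube$data)
  valid <- !is.na(cube$data)
  if (!any(valid)) abort_input("cannot write an all-nodata cube to TIFF")
  vals <- cube$data
  vals[!valid] <- 0
  v <- vals[valid]
  integral <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
  if (integral) {
    scale <- 65535; offset <- 0; bits <- 16L
  } else {
    offset <- min(v)
    scale <- if (max(v) > min(v)) max(v) - min(v) else 1
    bits <- 32L
  }
  stored <- (vals - offset) / scale
  stored[!valid] <- 0
  planes <- lapply(seq_len(d[3]), function(b) stored[, , b])
  # nodata is per-pixel in the mask plane: a pixel missing in any band is
  # masked everywhere (cross-band gaps are rare in practice)
  planes[[d[3] + 1]] <- matrix(as.numeric(apply(valid, c(1, 2), all)),
                               d[1], d[2])
  suppressWarnings(tiff::writeTIFF(planes, path, bits.per.sample = bits))
  sidecar <- list(wavelengths_nm = cube$wavelengths_nm, units = cube$units,
                  nodata = cube$nodata, scale = scale, offset = offset,
                  integral = integral, mask_plane = TRUE)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

read_cube_tiff <- function(path, wavelengths_nm = NULL) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::fromJSON(side_path, simplifyVector = TRUE) else list()
  mask <- NULL
  if (isTRUE(side$mask_plane)) {
    mask <- imgs[[length(imgs)]] >= 0.5
    imgs <- imgs[-length(imgs)]
  }
  wl <- wavelengths_nm %||% side$wavelengths_nm
  if (is.null(wl))
    abort_input(paste0("no wavelength metadata for ", path,
                       "; pass wavelengths_nm (CLI: --wavelengths)"))
  if (length(wl) != length(imgs))
    abort_input(sprintf("%d bands but %d listed wavelengths",
                        length(imgs), length(wl)))
  scale <- side$scale %||% 1; offset <- side$offset %||% 0
  arr <- simplify2array(imgs) * scale + offset
  if (isTRUE(side$integral)) arr <- round(arr)
  if (!is.null(mask))
    for (b in seq_len(dim(arr)[3])) {
      plane <- arr[, , b]
      plane[!mask] <- NA_real_
      arr[, , b] <- plane
    }
  hyper_cube(arr, wl, units = side$units %||% "DN",
             nodata = side$nodata %||% -9999)
}
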