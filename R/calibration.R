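# Empirical-line reflectance calibration: per-band ordinary least squares of
# known panel reflectance against mean panel digital number, applied as one
# multiply-add per pixel to turn a DN cube into a reflectance cube.

#' Reference panel specification
#'
#' A calibration panel of known reflectance occupying a pixel rectangle of
#' the cube. Reflectance may be a single value (flat spectrum) or a
#' per-band curve matching the cube's band count.
#'
#' @param label Panel name ("black", "gray", ...).
#' @param reflectance Fraction in \[0, 1\]; scalar or per-band vector.
#' @param rows,cols Integer ranges (inclusive) of the panel rectangle.
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(label, reflectance, rows, cols) {
  if (any(reflectance < 0) || any(reflectance > 1))
    abort_input("panel reflectance must be in [0, 1]")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (!length(rows) || !length(cols))
    abort_input("panel region must be nonempty")
  structure(list(label = label, reflectance = reflectance,
                 rows = range(rows), cols = range(cols)),
            class = "panel_spec")
}

#' Built-in panel reflectance presets
#'
#' `"mosaicmill"`: black 10%, gray 30%, white 57% (gray-scale fabric target
#' values). `"binary"`: black 0%, white 100%.
#'
#' @param preset Preset name.
#' @return Named numeric vector of reflectances.
#' @export
panel_presets <- function(preset = c("mosaicmill", "binary")) {
  preset <- match.arg(preset)
  switch(preset,
    mosaicmill = c(black = 0.10, gray = 0.30, white = 0.57),
    binary = c(black = 0.00, white = 1.00))
}

#' Read panel specs from a YAML/JSON file
#'
#' Expects a list of entries with `label`, `reflectance`, `rows` (two-element
#' range) and `cols`.
#'
#' @param path Panels file path.
#' @return List of [panel_spec()]s.
#' @export
read_panel_specs <- function(path) {
  cfg <- read_config(path)
  entries <- cfg$panels %||% cfg
  lapply(entries, function(e)
    panel_spec(e$label, as.numeric(e$reflectance),
               as.integer(e$rows), as.integer(e$cols)))
}

#' Mean panel digital numbers per band
#'
#' Averages the DN over each panel region, per band, excluding nodata pixels.
#'
#' @param cube A DN-unit [hyper_cube()].
#' @param panels List of [panel_spec()]s.
#' @return Matrix, `n_panels x n_bands`, with panel labels as row names.
#' @export
extract_panel_stats <- function(cube, panels) {
  if (cube$units != "DN")
    abort_input("panel statistics are extracted from a DN cube")
  d <- dim(cube$data)
  nb <- d[3]
  out <- matrix(NA_real_, nrow = length(panels), ncol = nb,
                dimnames = list(vapply(panels, `[[`, "", "label"), NULL))
  for (k in seq_along(panels)) {
    p <- panels[[k]]
    if (p$rows[2] > d[1] || p$cols[2] > d[2] || p$rows[1] < 1 || p$cols[1] < 1)
      abort_input(sprintf("panel '%s' region outside image bounds", p$label))
    block <- cube$data[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2], , drop = FALSE]
    m <- apply(block, 3, mean, na.rm = TRUE)
    if (anyNA(m) || any(is.nan(m)))
      abort_input(sprintf("panel '%s' region is fully nodata", p$label))
    out[k, ] <- m
  }
  out
}

#' Fit the empirical line per band
#'
#' Ordinary least squares of panel reflectance on mean panel DN,
#' independently for each band: `reflectance = gain * DN + offset`. With
#' exactly two panels the line interpolates both points. Requires at least
#' two panels with distinct mean DN in every band.
#'
#' @param panel_means Matrix from [extract_panel_stats()]
#'   (`n_panels x n_bands`).
#' @param panel_reflectances Numeric vector (flat spectra, one value per
#'   panel) or matrix (`n_panels x n_bands`).
#' @param wavelengths_nm Band wavelengths carried into the model.
#' @return A `calibration_model` with per-band `gain`, `offset`, `fit_r2`.
#' @export
fit_empirical_line <- function(panel_means, panel_reflectances,
                               wavelengths_nm = NULL) {
  np <- nrow(panel_means); nb <- ncol(panel_means)
  if (np < 2)
    abort_input("need at least 2 panels to fit the empirical line",
                class = "agrisurvey_degenerate_fit")
  refl <- if (is.matrix(panel_reflectances)) panel_reflectances
          else matrix(panel_reflectances, nrow = np, ncol = nb)
  gain <- offset <- r2 <- numeric(nb)
  for (b in seq_len(nb)) {
    dn <- panel_means[, b]; y <- refl[, b]
    if (diff(range(dn)) == 0)
      abort_input(sprintf("band %d: identical panel DNs, cannot fit", b),
                  class = "agrisurvey_degenerate_fit")
    fit <- stats::lm.fit(cbind(1, dn), y)
    offset[b] <- fit$coefficients[1]
    gain[b] <- fit$coefficients[2]
    ss_tot <- sum((y - mean(y))^2)
    r2[b] <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  }
  structure(list(gain = gain, offset = offset, fit_r2 = r2,
                 wavelengths_nm = wavelengths_nm),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %d bands, gain %.3g-%.3g, min r2 %.4f\n",
              length(x$gain), min(x$gain), max(x$gain), min(x$fit_r2)))
  invisible(x)
}

#' Apply an empirical-line correction to a DN cube
#'
#' Band-wise `reflectance = gain * DN + offset` for every pixel, nodata
#' propagated, output clipped to `clip` (default \[0, 1.5\]: keeps specular
#' outliers bounded without collapsing them to 1). The result is a new cube
#' flagged as reflectance.
#'
#' @param cube A DN-unit [hyper_cube()].
#' @param model A `calibration_model` with matching band count.
#' @param clip Two-element clipping interval, or `NULL` for no clipping.
#' @return A reflectance [hyper_cube()].
#' @export
apply_correction <- function(cube, model, clip = c(0, 1.5)) {
  if (cube$units == "reflectance")
    abort_input("cube is already reflectance; refusing to correct twice")
  nb <- dim(cube$data)[3]
  if (length(model$gain) != nb)
    abort_input(sprintf("model has %d bands, cube has %d",
                        length(model$gain), nb))
  out <- cube$data
  for (b in seq_len(nb))
    out[, , b] <- model$gain[b] * cube$data[, , b] + model$offset[b]
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  hyper_cube(out, cube$wavelengths_nm, units = "reflectance",
             nodata = cube$nodata)
}

#' One-call empirical-line calibration
#'
#' Extracts panel statistics, fits the per-band line, and applies it.
#'
#' @inheritParams extract_panel_stats
#' @inheritParams apply_correction
#' @return List with `cube` (reflectance) and `model`.
#' @export
calibrate_cube <- function(cube, panels, clip = c(0, 1.5)) {
  means <- extract_panel_stats(cube, panels)
  refl <- vapply(panels, function(p) p$reflectance[1], 0)
  refl_mat <- do.call(rbind, lapply(panels, function(p)
    if (length(p$reflectance) == 1)
      rep(p$reflectance, dim(cube$data)[3]) else p$reflectance))
  model <- fit_empirical_line(means, refl_mat, cube$wavelengths_nm)
  list(cube = apply_correction(cube, model, clip), model = model)
}
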