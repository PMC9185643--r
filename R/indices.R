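# Vegetation-index registry and per-pixel computation, plus threshold
# classification and histogramming of the resulting index maps.
#
# The registry is declarative data: each definition names its required bands
# (target wavelength + tolerance + role), its coefficients with defaults, and
# an arithmetic formula over band roles. Formulas follow the canonical
# literature definitions; every coefficient is overridable per call so the
# registry can be adapted without code changes.

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

band_req <- function(role, target_nm, tolerance_nm = 15)
  list(role = role, target_nm = target_nm, tolerance_nm = tolerance_nm)

index_def <- function(name, long_name, bands, fun, coefficients = NULL,
                      coefficients_required = FALSE, range_hint = c(-1, 1),
                      normalized_difference = FALSE, two_epoch = FALSE,
                      citation = "") {
  structure(list(name = name, long_name = long_name, bands = bands,
                 fun = fun, coefficients = coefficients,
                 coefficients_required = coefficients_required,
                 range_hint = range_hint,
                 normalized_difference = normalized_difference,
                 two_epoch = two_epoch, citation = citation),
            class = "index_definition")
}

nd_fun <- function(a, b) function(B, K) safe_div(B[[a]] - B[[b]], B[[a]] + B[[b]])

linear_combo_fun <- function(B, K) {
  if (is.null(K) || !length(K))
    abort_input("this chemometric index needs user-supplied coefficients")
  out <- if (!is.null(K[["intercept"]])) K[["intercept"]] else 0
  terms <- setdiff(names(K), "intercept")
  if (!length(terms))
    abort_input("coefficients must reference at least one band as w<nm>")
  out <- out + Reduce(`+`, lapply(terms, function(nm) K[[nm]] * B[[nm]]))
  out
}

#' The vegetation-index registry
#'
#' Eighteen index definitions: NDVI, RVI, EVI, SSC, SAVI, CCI, ARVI, GCI,
#' MCARI, DCNI, SIPI, NBR, DNBR, NDWI, PLS, PRI, PSRI and TA. Fifteen are
#' closed-form combinations of reflectance bands from the canonical
#' literature definitions (Rouse 1974 NDVI; Jordan 1969 RVI; Huete 2002 EVI;
#' Huete 1988 SAVI; Gamon & Berry CCI-style normalized difference; Kaufman &
#' Tanre 1992 ARVI; Gitelson 2003 GCI; Daughtry 2000 MCARI; Chen 2010 DCNI;
#' Penuelas 1995 SIPI; Key & Benson NBR/DNBR; Gao 1996 NDWI; Gamon 1992 PRI;
#' Merzlyak 1999 PSRI). SSC (soluble solid content), TA (titratable acidity)
#' and PLS (regression water-stress index) are chemometric regression indices
#' with no universal closed form: they are user-parameterized linear
#' combinations of named bands and require coefficients
#' (`c(intercept = ..., w860 = ..., ...)`). DNBR is a two-epoch index
#' (pre-fire minus post-fire NBR) and needs two cubes.
#'
#' DCNI's red-edge bands default to 750/705/680 nm so all closed-form indices
#' resolve against a standard 12-band set
#' (450, 531, 560, 570, 640, 680, 705, 750, 800, 860, 1240, 2200 nm).
#'
#' @return Named list of index definitions, length 18.
#' @export
index_registry <- function() {
  defs <- list(
    index_def("NDVI", "Normalized Difference Vegetation Index",
      list(band_req("NIR", 860), band_req("RED", 640)),
      nd_fun("NIR", "RED"), normalized_difference = TRUE,
      citation = "Rouse et al. 1974"),
    index_def("RVI", "Ratio Vegetation Index",
      list(band_req("NIR", 860), band_req("RED", 640)),
      function(B, K) safe_div(B$NIR, B$RED), range_hint = c(0, 30),
      citation = "Jordan 1969"),
    index_def("EVI", "Enhanced Vegetation Index",
      list(band_req("NIR", 860), band_req("RED", 640), band_req("BLUE", 450)),
      function(B, K) K$G * safe_div(B$NIR - B$RED,
                                    B$NIR + K$C1 * B$RED - K$C2 * B$BLUE + K$L),
      coefficients = c(G = 2.5, C1 = 6, C2 = 7.5, L = 1),
      citation = "Huete et al. 2002"),
    index_def("SSC", "Soluble Solid Content (chemometric regression)",
      list(), linear_combo_fun, coefficients_required = TRUE,
      range_hint = c(0, 25), citation = "user-calibrated PLS/linear model"),
    index_def("SAVI", "Soil Adjusted Vegetation Index",
      list(band_req("NIR", 860), band_req("RED", 640)),
      function(B, K) (1 + K$L) * safe_div(B$NIR - B$RED, B$NIR + B$RED + K$L),
      coefficients = c(L = 0.5), citation = "Huete 1988"),
    index_def("CCI", "Citrus/Chlorophyll-Carotenoid Color Index",
      list(band_req("G531", 531), band_req("RED", 640)),
      nd_fun("G531", "RED"), normalized_difference = TRUE,
      citation = "Gamon et al. 2016 (normalized-difference form)"),
    index_def("ARVI", "Atmospherically Resistant Vegetation Index",
      list(band_req("NIR", 860), band_req("RED", 640), band_req("BLUE", 450)),
      function(B, K) {
        rb <- B$RED - K$gamma * (B$BLUE - B$RED)
        safe_div(B$NIR - rb, B$NIR + rb)
      }, coefficients = c(gamma = 1), citation = "Kaufman & Tanre 1992"),
    index_def("GCI", "Green Chlorophyll Index",
      list(band_req("NIR", 860), band_req("GREEN", 560)),
      function(B, K) safe_div(B$NIR, B$GREEN) - 1, range_hint = c(0, 15),
      citation = "Gitelson et al. 2003"),
    index_def("MCARI", "Modified Chlorophyll Absorption in Reflectance Index",
      list(band_req("RE", 700), band_req("RED", 670), band_req("GREEN", 550)),
      function(B, K) ((B$RE - B$RED) - 0.2 * (B$RE - B$GREEN)) *
        safe_div(B$RE, B$RED),
      range_hint = c(0, 2), citation = "Daughtry et al. 2000"),
    index_def("DCNI", "Double-peak Canopy Nitrogen Index",
      list(band_req("RE2", 750), band_req("RE1", 705), band_req("RED", 680)),
      function(B, K) safe_div(safe_div(B$RE2 - B$RE1, B$RE1 - B$RED),
                              B$RE2 - B$RED + 0.03),
      range_hint = c(0, 100), citation = "Chen et al. 2010"),
    index_def("SIPI", "Structure Insensitive Pigment Index",
      list(band_req("NIR", 800), band_req("BLUE", 445), band_req("RED", 680)),
      function(B, K) safe_div(B$NIR - B$BLUE, B$NIR - B$RED),
      range_hint = c(0, 2), citation = "Penuelas et al. 1995"),
    index_def("NBR", "Normalized Burn (Calcination) Ratio",
      list(band_req("NIR", 860), band_req("SWIR2", 2200)),
      nd_fun("NIR", "SWIR2"), normalized_difference = TRUE,
      citation = "Key & Benson 2006"),
    index_def("DNBR", "Difference Normalized Burn Ratio (two-epoch)",
      list(band_req("NIR", 860), band_req("SWIR2", 2200)),
      nd_fun("NIR", "SWIR2"), normalized_difference = FALSE,
      two_epoch = TRUE, range_hint = c(-2, 2),
      citation = "Key & Benson 2006"),
    index_def("NDWI", "Normalized Difference Water Index",
      list(band_req("NIR", 860), band_req("SWIR1", 1240)),
      nd_fun("NIR", "SWIR1"), normalized_difference = TRUE,
      citation = "Gao 1996"),
    index_def("PLS", "Regression Water Stress Index (chemometric)",
      list(), linear_combo_fun, coefficients_required = TRUE,
      range_hint = c(0, 10), citation = "user-calibrated PLS model"),
    index_def("PRI", "Photochemical Reflectance Index",
      list(band_req("G531", 531), band_req("G570", 570)),
      nd_fun("G531", "G570"), normalized_difference = TRUE,
      citation = "Gamon et al. 1992"),
    index_def("PSRI", "Plant Senescence Reflectance Index",
      list(band_req("RED", 680), band_req("GREEN", 500, 35),
           band_req("RE", 750)),
      function(B, K) safe_div(B$RED - B$GREEN, B$RE),
      range_hint = c(-1, 1), citation = "Merzlyak et al. 1999"),
    index_def("TA", "Titratable Acidity (chemometric regression)",
      list(), linear_combo_fun, coefficients_required = TRUE,
      range_hint = c(0, 15), citation = "user-calibrated PLS/linear model")
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Look up one index definition
#' @param name Canonical abbreviation (e.g. `"NDVI"`).
#' @return An `index_definition`.
#' @export
index_lookup <- function(name) {
  reg <- index_registry()
  if (!name %in% names(reg))
    abort_input(paste0("unknown index: ", name, " (known: ",
                       paste(names(reg), collapse = ", "), ")"),
                class = "agrisurvey_unknown_index")
  reg[[name]]
}

resolve_bands <- function(cube, def, coefficients = NULL) {
  B <- list()
  for (req in def$bands) {
    b <- tryCatch(band_at(cube, req$target_nm, req$tolerance_nm),
      agrisurvey_missing_band = function(e)
        abort_input(sprintf("%s needs a band near %g nm: %s",
                            def$name, req$target_nm, conditionMessage(e)),
                    class = "agrisurvey_missing_band"))
    B[[req$role]] <- cube_band(cube, b)
  }
  # chemometric linear combinations reference bands as w<nm> coefficients
  for (nm in setdiff(names(coefficients), "intercept")) {
    wl <- suppressWarnings(as.numeric(sub("^w", "", nm)))
    if (!is.na(wl) && is.null(B[[nm]]))
      B[[nm]] <- cube_band(cube, band_at(cube, wl))
  }
  B
}

#' Compute a vegetation index over a reflectance cube
#'
#' Element-wise evaluation of the registered formula. Pixels where any input
#' band is nodata, or where a denominator is zero, are nodata in the result.
#' DN cubes are refused with a hint to calibrate first. `DNBR` needs a
#' second (post-epoch) cube.
#'
#' @param cube A reflectance [hyper_cube()].
#' @param name Index name from [index_registry()].
#' @param coefficients Named numeric overriding the definition defaults (or
#'   supplying them, for SSC/PLS/TA).
#' @param cube_post Second cube for the two-epoch DNBR.
#' @return An `index_map`: list with `values` matrix, `index_name`,
#'   `range_hint`, `provenance`.
#' @export
compute_index <- function(cube, name, coefficients = NULL, cube_post = NULL) {
  def <- index_lookup(name)
  if (cube$units == "DN")
    abort_input(paste0(name, " needs a reflectance cube; ",
                       "run the empirical-line calibration first"))
  K <- as.list(def$coefficients %||% numeric())
  for (nm in names(coefficients)) K[[nm]] <- coefficients[[nm]]
  if (def$coefficients_required && !length(K))
    abort_input(sprintf(
      "%s is a user-parameterized regression index: supply coefficients",
      name))
  if (def$two_epoch) {
    if (is.null(cube_post))
      abort_input(paste0(name, " is a two-epoch index: supply cube_post"))
    pre <- def$fun(resolve_bands(cube, def, coefficients), K)
    post <- def$fun(resolve_bands(cube_post, def, coefficients), K)
    values <- pre - post
  } else {
    values <- def$fun(resolve_bands(cube, def, coefficients), K)
  }
  structure(list(values = values, index_name = name,
                 range_hint = def$range_hint,
                 provenance = list(
                   wavelengths_nm = cube$wavelengths_nm,
                   bands = vapply(def$bands, `[[`, 0, "target_nm"),
                   coefficients = K)),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("index_map %s: %d x %d, %d valid px, range [%.4f, %.4f]\n",
              x$index_name, nrow(x$values), ncol(x$values), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Default classification rules for an index
#'
#' NDVI defaults to healthy vegetation above 0.3: `not_healthy` on
#' `(-Inf, 0.3]`, `healthy` on `(0.3, Inf)` (boundaries are lower-exclusive /
#' upper-inclusive, so a pixel exactly at 0.3 is `not_healthy`).
#'
#' @param index_name Index name.
#' @return Data frame with columns `label`, `lower`, `upper`.
#' @export
default_rules <- function(index_name = "NDVI") {
  data.frame(label = c("not_healthy", "healthy"),
             lower = c(-Inf, 0.3), upper = c(0.3, Inf),
             stringsAsFactors = FALSE)
}

#' Classify an index map into labeled ranges
#'
#' Each rule covers the half-open interval `(lower, upper]`; rules must not
#' overlap. Nodata pixels stay unlabeled (`NA`); class counts sum to the
#' number of valid pixels that fall in some interval.
#'
#' @param map An `index_map`.
#' @param rules Data frame `label`, `lower`, `upper`;
#'   default [default_rules()] for the map's index.
#' @return List with `labels` (character matrix) and `counts` (named integer).
#' @export
classify <- function(map, rules = NULL) {
  rules <- rules %||% default_rules(map$index_name)
  if (nrow(rules) > 1) {
    o <- order(rules$lower)
    r <- rules[o, ]
    if (any(r$upper[-nrow(r)] > r$lower[-1]))
      abort_input("classification intervals overlap",
                  class = "agrisurvey_invalid_rules")
  }
  v <- map$values
  labels <- matrix(NA_character_, nrow(v), ncol(v))
  for (k in seq_len(nrow(rules)))
    labels[!is.na(v) & v > rules$lower[k] & v <= rules$upper[k]] <-
      rules$label[k]
  counts <- vapply(rules$label, function(l) sum(labels == l, na.rm = TRUE), 0L)
  list(labels = labels, counts = counts)
}

#' Histogram of an index map
#'
#' Bins the valid (non-nodata) pixels. Normalized-difference indices default
#' to fixed `[-1, 1]` edges; others span the observed range.
#'
#' @param map An `index_map`.
#' @param n_bins Number of equal-width bins (ignored when `edges` given).
#' @param edges Explicit bin edges (increasing).
#' @return List with `edges`, `counts`, `n_valid`; counts sum to `n_valid`.
#' @export
index_histogram <- function(map, n_bins = 10, edges = NULL) {
  v <- map$values[!is.na(map$values)]
  if (!length(v)) abort_input("all pixels are nodata; nothing to bin")
  if (is.null(edges)) {
    if (n_bins < 1) abort_input("n_bins must be >= 1")
    def <- index_lookup(map$index_name)
    rng <- if (def$normalized_difference) c(-1, 1) else range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  # clamp into the covered range so counts always sum to n_valid
  v <- pmin(pmax(v, edges[1]), edges[length(edges)])
  h <- graphics::hist(v, breaks = edges, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  list(edges = h$breaks, counts = h$counts, n_valid = length(v))
}
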