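# Pseudo-color rendering of index maps, histogram plots, and PDF report
# assembly for offline consultation.

#' Colormap lookup
#'
#' `"vegetation"` (default) ramps red (low) through yellow to green (high),
#' the conventional rendering for vegetation vigor; `"gray"` and `"viridis"`
#' (dark blue to yellow) are also available.
#'
#' @param name Colormap name.
#' @param n Number of colors.
#' @return Character vector of `n` hex colors.
#' @export
colormap_colors <- function(name = "vegetation", n = 256) {
  pal <- switch(name,
    vegetation = c("#a50026", "#d73027", "#f46d43", "#fdae61", "#fee08b",
                   "#d9ef8b", "#a6d96a", "#66bd63", "#1a9850", "#006837"),
    gray = c("#000000", "#ffffff"),
    viridis = c("#440154", "#31688e", "#35b779", "#fde725"),
    abort_input(paste0("unknown colormap: ", name)))
  grDevices::colorRampPalette(pal)(n)
}

map_to_rgba <- function(map, colormap = "vegetation",
                        vmin = NULL, vmax = NULL) {
  v <- map$values
  if (all(is.na(v))) abort_input("all pixels are nodata; nothing to render")
  vmin <- vmin %||% map$range_hint[1]
  vmax <- vmax %||% map$range_hint[2]
  if (vmax <= vmin) abort_input("vmax must exceed vmin")
  cols <- colormap_colors(colormap)
  t01 <- pmin(pmax((v - vmin) / (vmax - vmin), 0), 1)
  idx <- pmin(floor(t01 * length(cols)) + 1, length(cols))
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, dim = c(nrow(v), ncol(v), 4))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(v), ncol(v))
    plane[ok] <- rgb[ch, idx[ok]]
    arr[, , ch] <- plane
  }
  alpha <- matrix(0, nrow(v), ncol(v))
  alpha[ok] <- 1            # nodata rendered transparent
  arr[, , 4] <- alpha
  arr
}

#' Render an index map as a pseudo-color PNG
#'
#' Linear value-to-color mapping over `[vmin, vmax]` (defaults to the
#' index's expected range); values outside are clamped to the endpoint
#' colors; nodata pixels are transparent. Output bytes are deterministic for
#' identical inputs.
#'
#' @param map An `index_map`.
#' @param path Output PNG path.
#' @param colormap Colormap name, see [colormap_colors()].
#' @param vmin,vmax Value range mapped onto the colormap.
#' @return `path`, invisibly.
#' @export
render_pseudocolor <- function(map, path, colormap = "vegetation",
                               vmin = NULL, vmax = NULL) {
  arr <- map_to_rgba(map, colormap, vmin, vmax)
  png::writePNG(arr, path)
  invisible(path)
}

#' Render an index-map histogram as a PNG
#'
#' Bar plot of [index_histogram()]; with classification rules the bars are
#' colored by the class their bin falls in.
#'
#' @param map An `index_map`.
#' @param path Output PNG path.
#' @param n_bins Number of bins.
#' @param rules Optional classification rules (see [classify()]).
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_histogram <- function(map, path, n_bins = 20, rules = NULL,
                             width = 640, height = 480) {
  h <- index_histogram(map, n_bins = n_bins)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  plot_histogram(h, map$index_name, rules)
  invisible(path)
}

plot_histogram <- function(h, index_name, rules = NULL) {
  mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
  col <- rep("#4d9221", length(mids))
  legend_labs <- NULL
  if (!is.null(rules)) {
    pal <- grDevices::colorRampPalette(c("#c51b7d", "#e9a3c9", "#a1d76a",
                                         "#4d9221"))(nrow(rules))
    for (k in seq_len(nrow(rules)))
      col[mids > rules$lower[k] & mids <= rules$upper[k]] <- pal[k]
    legend_labs <- rules$label
  }
  graphics::barplot(h$counts, names.arg = sprintf("%.2f", mids),
                    col = col, border = NA, las = 2, cex.names = 0.7,
                    main = paste(index_name, "histogram"),
                    xlab = index_name, ylab = "pixel count")
  if (!is.null(legend_labs))
    graphics::legend("topleft", legend = legend_labs,
                     fill = grDevices::colorRampPalette(
                       c("#c51b7d", "#e9a3c9", "#a1d76a", "#4d9221"))(
                       length(legend_labs)),
                     bty = "n", cex = 0.8)
}

#' Assemble a PDF report for a set of index maps
#'
#' One metadata page followed by one page per index (pseudo-color rendering,
#' histogram, class counts). Page count is therefore `1 + n_indices`.
#' Regeneration with identical inputs is idempotent on content (the PDF
#' creation/modification timestamps differ).
#'
#' @param maps Named list of `index_map`s (at least one).
#' @param path Output PDF path.
#' @param metadata Named list of mission metadata shown on the first page.
#' @param colormap Colormap for the pseudo-color panels.
#' @param n_bins Histogram bins.
#' @param rules_for Function `index_name -> rules` or `NULL`; by default NDVI
#'   gets its healthy/not-healthy rules, other indices are unclassified.
#' @return `path`, invisibly.
#' @export
build_report <- function(maps, path, metadata = list(),
                         colormap = "vegetation", n_bins = 20,
                         rules_for = NULL) {
  if (!length(maps)) abort_input("report needs at least one index map")
  bad <- !vapply(maps, inherits, TRUE, "index_map")
  if (any(bad)) abort_input("maps must be index_map objects")
  rules_for <- rules_for %||% function(nm)
    if (nm == "NDVI") default_rules(nm) else NULL
  grDevices::pdf(path, width = 8.27, height = 11.69, onefile = TRUE,
                 useDingbats = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  # page 1: mission metadata
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot.new()
  graphics::title(main = "Survey report", cex.main = 1.6)
  lines <- c(sprintf("indices: %s",
                     paste(vapply(maps, `[[`, "", "index_name"),
                           collapse = ", ")),
             vapply(names(metadata), function(k)
               sprintf("%s: %s", k, paste(format(metadata[[k]]),
                                          collapse = " ")), ""))
  graphics::text(0, seq(0.95, by = -0.05, length.out = length(lines)),
                 lines, adj = 0, cex = 0.9)
  for (map in maps) {
    rules <- rules_for(map$index_name)
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::layout(matrix(c(1, 2), nrow = 2), heights = c(1.2, 1))
    arr <- map_to_rgba(map, colormap)
    arr <- downsample_rgba(arr, 2048)
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = ncol(
      map$values) / nrow(map$values))
    graphics::rasterImage(arr, 0, 0, 1, 1, interpolate = FALSE)
    graphics::title(main = map$index_name)
    h <- index_histogram(map, n_bins = n_bins)
    plot_histogram(h, map$index_name, rules)
    if (!is.null(rules)) {
      counts <- classify(map, rules)$counts
      graphics::mtext(paste(sprintf("%s: %d", names(counts), counts),
                            collapse = "   "), side = 1, line = 3.5,
                      cex = 0.8)
    }
    graphics::layout(1)
  }
  invisible(path)
}

downsample_rgba <- function(arr, max_px) {
  d <- dim(arr)
  f <- ceiling(max(d[1:2]) / max_px)
  if (f <= 1) return(arr)
  arr[seq(1, d[1], by = f), seq(1, d[2], by = f), , drop = FALSE]
}

#' Count the pages of a PDF file
#'
#' Reads the `/Count` entry of the page tree; used to check report layout.
#'
#' @param path PDF path.
#' @return Integer page count.
#' @export
pdf_page_count <- function(path) {
  lines <- readLines(path, warn = FALSE, skipNul = TRUE)
  hits <- regmatches(lines, regexpr("/Count \\d+", lines, useBytes = TRUE))
  hits <- unlist(hits)
  if (!length(hits)) abort_input("no /Count entry found; not a paged PDF?")
  max(as.integer(sub("/Count ", "", hits)))
}
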