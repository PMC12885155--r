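#' Rendering options for the Guttman error map
#'
#' Collects the graphical arguments of the map with their defaults: title
#' and fonts, axis/label/value sizes (ggplot2 units; `valsize = 0`
#' suppresses the value annotations), the printf-style format of the
#' annotated percentages, item-label position (`"top"` is recommended for
#' vertical reading of the errors away from the empty diagonal), legend
#' placement/title/relative size, smoothing level 0..100, and the optional
#' display of the item coefficients under the labels (`tith`) and of the
#' scale H in the title (`itemh`).
#'
#' @param title plot title (default `"Guttman Error Map"`).
#' @param font font family; `NULL`/`NA` falls back to `"serif"` with a
#'   warning.
#' @param titsize,xlabsize,ylabsize font sizes in points (defaults 18, 12,
#'   12).
#' @param valsize size of the in-cell percentage values (default 3.5,
#'   ggplot2 text units); 0 removes them.
#' @param valformat sprintf format for the values (default `"%.1f"`).
#' @param item_position `"bottom"` (default) or `"top"`.
#' @param legposit `"bottom"` (default), `"right"`, `"left"`, `"top"` or
#'   `"none"`.
#' @param legtit legend title (default `"% error"`).
#' @param legsize legend size as percent of its full size (default 100).
#' @param smooth smoothing level in `[0, 100]`: 0 is the discrete heatmap,
#'   100 a continuous gradient, intermediate values blend the two.
#' @param tith show item h_i under the item labels (default `FALSE`).
#' @param itemh show the scale H in the title (default `FALSE`).
#' @param scheme a [band_scheme()] supplying bands and gradient.
#' @param res pixels per cell side for the smoothed field (odd, so cell
#'   centres are sampled; default 11).
#' @return a list of class `render_options`.
#' @export
render_options <- function(title = "Guttman Error Map",
                           font = "Times New Roman",
                           titsize = 18, xlabsize = 12, ylabsize = 12,
                           valsize = 3.5, valformat = "%.1f",
                           item_position = c("bottom", "top"),
                           legposit = c("bottom", "right", "left", "top", "none"),
                           legtit = "% error", legsize = 100,
                           smooth = 0, tith = FALSE, itemh = FALSE,
                           scheme = band_scheme(), res = 11) {
  if (is.null(font) || is.na(font)) {
    warning("font family unavailable; falling back to \"serif\"",
            call. = FALSE)
    font <- "serif"
  }
  if (!is.numeric(smooth) || smooth < 0 || smooth > 100)
    stop("`smooth` must lie in [0, 100]", call. = FALSE)
  stopifnot(valsize >= 0, res >= 1)
  structure(list(
    title = title, font = font, titsize = titsize, xlabsize = xlabsize,
    ylabsize = ylabsize, valsize = valsize, valformat = valformat,
    item_position = match.arg(item_position),
    legposit = match.arg(legposit), legtit = legtit, legsize = legsize,
    smooth = smooth, tith = tith, itemh = itemh, scheme = scheme,
    res = as.integer(res)), class = "render_options")
}

# bilinear interpolation of cell-centre values at coordinates (x, y) in
# cell units (cell i spans (i-1, i), centre at i - 0.5); NA centres
# (the diagonal) are excluded from the support and the remaining corner
# weights renormalised; beyond the outer centres values clamp
interp_centers <- function(M, x, y) {
  k <- nrow(M)
  gx <- pmin(pmax(x + 0.5, 1), k)   # centre-grid coordinates in [1, k]
  gy <- pmin(pmax(y + 0.5, 1), k)
  i0 <- pmin(floor(gy), k - 1L); fi <- gy - i0
  j0 <- pmin(floor(gx), k - 1L); fj <- gx - j0
  v00 <- M[cbind(i0, j0)];         w00 <- (1 - fi) * (1 - fj)
  v01 <- M[cbind(i0, j0 + 1L)];    w01 <- (1 - fi) * fj
  v10 <- M[cbind(i0 + 1L, j0)];    w10 <- fi * (1 - fj)
  v11 <- M[cbind(i0 + 1L, j0 + 1L)]; w11 <- fi * fj
  V <- cbind(v00, v01, v10, v11)
  W <- cbind(w00, w01, w10, w11)
  W[is.na(V)] <- 0
  V[is.na(V)] <- 0
  tot <- rowSums(W)
  out <- rowSums(V * W) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Smoothed value field of an error map
#'
#' Computes the per-pixel value field underlying the coloured surface of
#' the map at a given smoothing level: `smooth = 0` is the blockwise
#' constant field (each pixel takes its cell's e_ij), `smooth = 100` the
#' bilinear interpolation of the cell-centre values (with the empty
#' diagonal excluded from the interpolation support), and an intermediate
#' level `t` the per-pixel convex combination
#' `(1 - t/100) * discrete + (t/100) * continuous`. Diagonal-cell pixels
#' are masked (`NA`) at every smoothing level.
#'
#' @param em an [error_matrix()] result.
#' @param smooth smoothing level in `[0, 100]`.
#' @param res pixels per cell side (odd values sample the cell centres).
#' @return a `(k*res) x (k*res)` numeric matrix of field values; row/column
#'   position `(p, q)` corresponds to the point `((p-0.5)/res, (q-0.5)/res)`
#'   in cell units, rows running down the item ordering.
#' @export
smooth_field <- function(em, smooth, res = 11) {
  stopifnot(inherits(em, "error_map"))
  if (!is.numeric(smooth) || length(smooth) != 1L || smooth < 0 || smooth > 100)
    stop("`smooth` must lie in [0, 100]", call. = FALSE)
  M <- em$e_percent
  k <- nrow(M)
  u <- (seq_len(k * res) - 0.5) / res        # pixel-centre coordinates
  cell <- ceiling(u)                          # containing cell index
  D <- M[cell, cell, drop = FALSE]            # discrete field
  grid <- expand.grid(y = u, x = u)           # column-major like D
  C <- matrix(interp_centers(M, grid$x, grid$y), k * res, k * res)
  t <- smooth / 100
  out <- (1 - t) * D + t * C
  diag_mask <- outer(cell, cell, `==`)        # mask the empty diagonal
  out[diag_mask] <- NA_real_
  dimnames(out) <- NULL
  out
}

#' Render the Guttman error map
#'
#' Draws the symmetric annotated heatmap: a k x k grid in the item
#' ordering, each off-diagonal cell coloured along the traffic-light
#' gradient by its e_ij percentage and annotated with the formatted value,
#' identical in both triangles, the diagonal left empty. Smoothing replaces
#' the colour blocks by the blended continuous field of [smooth_field()]
#' without changing any annotated value.
#'
#' @param em an [error_matrix()] result.
#' @param hs the matching [loevinger()] result (used for `tith`/`itemh`).
#' @param opts a [render_options()] list.
#' @return a ggplot object.
#' @export
render_map <- function(em, hs, opts = render_options()) {
  stopifnot(inherits(em, "error_map"), inherits(hs, "h_summary"))
  M <- em$e_percent
  k <- nrow(M)
  labs_x <- em$labels
  if (isTRUE(opts$tith))
    labs_x <- sprintf("%s\nh=%.2f", labs_x, hs$h_item)
  stops <- opts$scheme$stops
  fill_scale <- ggplot2::scale_fill_gradientn(
    colours = stops$color, values = stops$value / 100,
    limits = c(0, 100), oob = function(x, ...) pmin(pmax(x, 0), 100),
    na.value = "white", name = opts$legtit)

  # cell (i, j): x = j, y = k + 1 - i so the first ordered item is top-left
  cells <- expand.grid(i = seq_len(k), j = seq_len(k))
  cells$e <- M[cbind(cells$i, cells$j)]
  cells <- cells[cells$i != cells$j & !is.na(cells$e), ]
  cells$x <- cells$j
  cells$y <- k + 1 - cells$i

  p <- ggplot2::ggplot()
  if (opts$smooth == 0) {
    p <- p + ggplot2::geom_tile(
      data = cells, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$e))
  } else {
    fld <- smooth_field(em, opts$smooth, opts$res)
    np <- nrow(fld)
    u <- (seq_len(np) - 0.5) / np * k
    px <- expand.grid(yy = u, xx = u)
    px$value <- as.vector(fld)
    px <- px[!is.na(px$value), ]
    px$x <- px$xx + 0.5
    px$y <- k - px$yy + 0.5
    # tiles, not a raster image: keeps vector output free of embedded
    # bitmaps whose ids vary across devices (byte-stable SVG)
    p <- p + ggplot2::geom_tile(
      data = px, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value),
      width = k / np, height = k / np)
  }
  if (opts$valsize > 0) {
    cells$lab <- sprintf(opts$valformat, cells$e)
    p <- p + ggplot2::geom_text(
      data = cells, ggplot2::aes(x = .data$x, y = .data$y, label = .data$lab),
      size = opts$valsize, family = opts$font)
  }
  title <- opts$title
  if (isTRUE(opts$itemh))
    title <- sprintf("%s (H = %.3f)", title, hs$h_total)
  p <- p + fill_scale +
    ggplot2::scale_x_continuous(breaks = seq_len(k), labels = labs_x,
                                expand = c(0, 0),
                                position = opts$item_position) +
    ggplot2::scale_y_continuous(breaks = rev(seq_len(k)), labels = em$labels,
                                expand = c(0, 0)) +
    ggplot2::coord_fixed(xlim = c(0.5, k + 0.5), ylim = c(0.5, k + 0.5)) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_family = opts$font) +
    ggplot2::theme(
      plot.title = ggplot2::element_text(size = opts$titsize, hjust = 0.5),
      axis.text.x = ggplot2::element_text(size = opts$xlabsize),
      axis.text.y = ggplot2::element_text(size = opts$ylabsize),
      panel.grid = ggplot2::element_blank(),
      legend.position = if (opts$legposit == "none") "none" else opts$legposit)
  if (opts$legposit %in% c("bottom", "top")) {
    p <- p + ggplot2::guides(fill = ggplot2::guide_colorbar(
      display = "rectangles", nbin = 100,
      barwidth = grid::unit(10 * opts$legsize / 100, "cm"),
      barheight = grid::unit(0.5 * opts$legsize / 100, "cm")))
  } else if (opts$legposit %in% c("left", "right")) {
    p <- p + ggplot2::guides(fill = ggplot2::guide_colorbar(
      display = "rectangles", nbin = 100,
      barheight = grid::unit(10 * opts$legsize / 100, "cm"),
      barwidth = grid::unit(0.5 * opts$legsize / 100, "cm")))
  }
  p
}

#' Export a map figure to a file
#'
#' Writes the figure in one of the supported formats; SVG is the default
#' vector format so downstream editors can convert the drawing into
#' editable objects.
#'
#' @param fig a ggplot object (from [render_map()]).
#' @param path output file path.
#' @param format one of `"svg"`, `"pdf"`, `"png"`, `"ps"`, `"jpg"`.
#' @param width,height device size in inches (default 7 x 7).
#' @param dpi raster resolution for png/jpg (default 300).
#' @return `path`, invisibly.
#' @export
export_map <- function(fig, path, format = c("svg", "pdf", "png", "ps", "jpg"),
                       width = 7, height = 7, dpi = 300) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  switch(format,
    svg = svg(path, width = width, height = height),
    pdf = pdf(path, width = width, height = height),
    png = png(path, width = width, height = height, units = "in", res = dpi),
    ps  = grDevices::cairo_ps(path, width = width, height = height),
    jpg = jpeg(path, width = width, height = height, units = "in", res = dpi))
  on.exit(dev.off())
  print(fig)
  invisible(path)
}
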