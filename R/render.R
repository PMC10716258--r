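#' Fixed-bin contact counts for a viewport
#'
#' Counts read pairs per square bin of `bin_size` bp. For on-diagonal
#' viewports the matrix is completed symmetrically: each off-diagonal
#' pair also counts into its mirror bin (once per cell it lands in).
#'
#' @param pairs Pairs tibble or an `x`/`y` point data frame.
#' @param viewport A [viewport()].
#' @param bin_size Bin side in bp; must give at least 2 bins per axis.
#' @return A `cc_heatmap` count matrix (rows = x bins, columns = y
#'   bins) with attributes `viewport` and `bin_size`.
#' @export
heatmap_counts <- function(pairs, viewport, bin_size) {
  span_x <- viewport$end_x - viewport$start_x
  span_y <- viewport$end_y - viewport$start_y
  if (bin_size > min(span_x, span_y)) {
    abort("bin size exceeds the viewport span")
  }
  if (bin_size > min(span_x, span_y) / 2) {
    abort("bin size must give at least 2 bins per axis")
  }
  pts <- clip_points_to_viewport(as_points(pairs, viewport), viewport)
  nx <- ceiling(span_x / bin_size)
  ny <- ceiling(span_y / bin_size)
  ix <- pmin(floor((pts$x - viewport$start_x) / bin_size) + 1L, nx)
  iy <- pmin(floor((pts$y - viewport$start_y) / bin_size) + 1L, ny)
  if (viewport_on_diagonal(viewport)) {
    # symmetric completion: every pair strictly off the diagonal also
    # counts at its mirror position (which may be the same bin)
    off <- pts$x != pts$y
    mx <- iy[off]; my <- ix[off]
    ix <- c(ix, mx); iy <- c(iy, my)
  }
  m <- matrix(0L, nx, ny)
  if (length(ix) > 0) {
    t <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
    m <- matrix(as.integer(t), nx, ny)
  }
  structure(m, class = c("cc_heatmap", "matrix"),
            viewport = viewport, bin_size = bin_size)
}

# sqrt transform + quantile saturation shared by heatmap displays
transform_counts <- function(m, saturation = 0.999, diag_width = 1,
                             transform = sqrt) {
  vp <- attr(m, "viewport")
  v <- unclass(m)
  if (!is.null(vp) && viewport_on_diagonal(vp) && diag_width >= 0) {
    idx <- abs(row(v) - col(v)) <= diag_width
    v[idx] <- 0
  }
  v <- transform(v)
  nz <- v[v > 0]
  if (length(nz) > 0) {
    cap <- quantile(nz, saturation, names = FALSE)
    v <- pmin(v, cap)
  }
  v
}

#' Plot a fixed-bin contact heatmap
#'
#' Applies the conventional display transform: on-diagonal viewports
#' have the diagonal band (width `diag_width` bins, default diagonal +
#' nearest neighbours) removed, counts are square-root transformed, and
#' colours saturate at the `saturation` quantile (default 99.9%) of the
#' nonzero transformed values.
#'
#' @param counts A `cc_heatmap` from [heatmap_counts()].
#' @param saturation Saturation quantile in (0, 1].
#' @param diag_width Diagonal-removal half-width in bins (`-1` disables).
#' @param transform Count transform function (default `sqrt`).
#' @return A ggplot object.
#' @export
plot_heatmap <- function(counts, saturation = 0.999, diag_width = 1,
                         transform = sqrt) {
  stopifnot(saturation > 0, saturation <= 1)
  vp <- attr(counts, "viewport")
  bs <- attr(counts, "bin_size")
  v <- transform_counts(counts, saturation, diag_width, transform)
  if (all(v == 0)) warn("all-zero heatmap; rendering a blank image")
  df <- tidyr::expand_grid(i = seq_len(nrow(v)), j = seq_len(ncol(v)))
  df$value <- v[cbind(df$i, df$j)]
  df$x <- vp$start_x + (df$i - 0.5) * bs
  df$y <- vp$start_y + (df$j - 0.5) * bs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "sqrt(count)") +
    ggplot2::scale_y_reverse(expand = c(0, 0),
                             labels = label_bp) +
    ggplot2::scale_x_continuous(expand = c(0, 0), labels = label_bp) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = vp$chrom_x, y = vp$chrom_y) +
    ggplot2::theme_minimal()
}

label_bp <- function(x) format(x, big.mark = ",", scientific = FALSE)

#' @export
autoplot.cc_heatmap <- function(object, ...) plot_heatmap(object, ...)

polygons_long <- function(diagram) {
  cells <- diagram$cells
  n_per <- vapply(cells$polygon, nrow, integer(1))
  tibble(cell = rep(seq_len(nrow(cells)), n_per),
         x = unlist(lapply(cells$polygon, function(p) p[, 1])),
         y = unlist(lapply(cells$polygon, function(p) p[, 2])),
         area = rep(cells$area, n_per))
}

#' Plot a Voronoi diagram coloured by cell area
#'
#' Cells are filled by a monotone colour map of log area, smaller area
#' (higher density) hotter. Optional annotation intervals are drawn as
#' track marks along the axes. Fallback-binned results delegate to the
#' heatmap display.
#'
#' @param diagram A `voronoi_diagram` (or `binned_density`).
#' @param tracks Optional tibble `start`, `end`, `axis` (`"x"`/`"y"`,
#'   bp) of annotation intervals.
#' @param linewidth Cell border width (0 disables borders).
#' @return A ggplot object.
#' @export
plot_voronoi <- function(diagram, tracks = NULL, linewidth = 0) {
  if (inherits(diagram, "binned_density")) {
    m <- structure(diagram$counts, class = c("cc_heatmap", "matrix"),
                   viewport = diagram$viewport,
                   bin_size = (diagram$viewport$end_x -
                                 diagram$viewport$start_x) /
                     diagram$resolution)
    return(plot_heatmap(m))
  }
  stopifnot(inherits(diagram, "voronoi_diagram"))
  vp <- diagram$viewport
  df <- polygons_long(diagram)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$cell,
                                        fill = log(.data$area))) +
    ggplot2::geom_polygon(colour = if (linewidth > 0) "grey30" else NA,
                          linewidth = linewidth) +
    ggplot2::scale_fill_viridis_c(option = "magma", direction = 1,
                                  name = "log area") +
    ggplot2::scale_y_reverse(expand = c(0, 0), labels = label_bp) +
    ggplot2::scale_x_continuous(expand = c(0, 0), labels = label_bp) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = vp$chrom_x, y = vp$chrom_y) +
    ggplot2::theme_minimal()
  if (!is.null(tracks) && nrow(tracks) > 0) {
    h <- 0.015 * (vp$end_x - vp$start_x)
    tx <- tracks[tracks$axis == "x", ]
    ty <- tracks[tracks$axis == "y", ]
    if (nrow(tx) > 0) {
      p <- p + ggplot2::annotate("rect", xmin = tx$start, xmax = tx$end,
                                 ymin = vp$start_y - h, ymax = vp$start_y,
                                 fill = "grey40")
    }
    if (nrow(ty) > 0) {
      p <- p + ggplot2::annotate("rect", ymin = ty$start, ymax = ty$end,
                                 xmin = vp$start_x - h, xmax = vp$start_x,
                                 fill = "grey40")
    }
  }
  p
}

#' @export
autoplot.voronoi_diagram <- function(object, ...) plot_voronoi(object, ...)

#' @export
autoplot.binned_density <- function(object, ...) plot_voronoi(object, ...)

# rigid rotation taking the diagonal to the horizontal baseline
rotate_triangle <- function(x, y, origin) {
  u <- ((x - origin) + (y - origin)) / sqrt(2)
  v <- ((y - origin) - (x - origin)) / sqrt(2)
  list(u = u, v = v)
}

#' Triangle view of an on-diagonal Voronoi diagram
#'
#' Rotates the upper triangle by 45 degrees so the diagonal becomes the
#' horizontal baseline, letting a wider stretch of the chromosome fit
#' one figure; the rotation is rigid, so cell areas are unchanged.
#'
#' @param diagram A `voronoi_diagram` over a square on-diagonal
#'   viewport.
#' @return A ggplot object; the rendered width spans `sqrt(2)` times
#'   the viewport span.
#' @export
plot_triangle <- function(diagram) {
  stopifnot(inherits(diagram, "voronoi_diagram"))
  vp <- diagram$viewport
  if (!viewport_on_diagonal(vp)) {
    abort("triangle view requires a square on-diagonal viewport")
  }
  df <- polygons_long(diagram)
  keep_cells <- which(with(diagram$cells, y >= x))
  df <- df[df$cell %in% keep_cells, ]
  rot <- rotate_triangle(df$x, df$y, vp$start_x)
  df$u <- rot$u; df$v <- rot$v
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   group = .data$cell,
                                   fill = log(.data$area))) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "log area") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = sprintf("%s (rotated bp)", vp$chrom_x), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an aggregate pileup on a log2 colour scale
#'
#' @param object A `cc_pileup` matrix (single or aggregate).
#' @param ... Unused.
#' @return A ggplot object showing log2 observed/expected.
#' @export
autoplot.cc_pileup <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- log2(m[cbind(df$i, df$j)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  name = "log2 obs/exp") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Save a figure deterministically by file extension
#'
#' `.svg` uses the cairo SVG device (byte-stable for identical input),
#' `.png` the PNG device, `.pdf` the PDF device.
#'
#' @param plot A ggplot object.
#' @param path Output path ending in `.svg`, `.png` or `.pdf`.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG.
#' @return `path`, invisibly.
#' @export
save_figure <- function(plot, path, width = 7, height = 7, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * dpi, height = height * dpi,
                         res = dpi),
    pdf = grDevices::pdf(path, width = width, height = height),
    abort(sprintf("unsupported figure format '.%s'", ext)))
  print(plot)
  grDevices::dev.off()
  invisible(path)
}
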