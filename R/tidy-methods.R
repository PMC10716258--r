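#' Tidy a Voronoi diagram into a per-cell tibble
#'
#' @param x A `voronoi_diagram`.
#' @param polygons Include the polygon vertex list-column.
#' @param ... Unused.
#' @return A tibble with one row per cell: seed coordinates,
#'   `multiplicity`, `area`, `density`, centroid, and optionally the
#'   clipped `polygon` vertices.
#' @export
tidy.voronoi_diagram <- function(x, polygons = FALSE, ...) {
  out <- x$cells
  if (!polygons) out$polygon <- NULL
  out
}

#' @rdname tidy.voronoi_diagram
#' @return `glance()` returns a one-row summary: cell count, retained
#'   pair count (total multiplicity), total cell area, viewport area
#'   and mode.
#' @export
glance.voronoi_diagram <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         n_pairs = sum(x$cells$multiplicity),
         total_area = sum(x$cells$area),
         viewport_area = viewport_area(x$viewport),
         mode = x$mode)
}

#' Tidy the robust background fit
#'
#' @param x A `cc_background_fit`.
#' @param ... Unused.
#' @return Coefficient tibble in broom layout (`term`, `estimate`).
#' @export
tidy.cc_background_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "log_distance"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.cc_background_fit
#' @export
glance.cc_background_fit <- function(x, ...) {
  tibble(scale = x$scale, n = x$n, estimator = x$estimator,
         converged = x$converged)
}
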