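#' Centroidal Voronoi smoothing by Lloyd iteration
#'
#' One Lloyd step replaces every seed by the area centroid of its clipped
#' Voronoi cell and rebuilds the diagram from the centroids; cell
#' multiplicities move with their centroids (mass is conserved, never
#' re-split). Iterating drives the tessellation toward a centroidal
#' Voronoi tessellation, locally equalizing cell areas, which makes
#' clusters of read pairs easier to see at a glance.
#'
#' @param diagram A `voronoi_diagram` in `full` mode.
#' @return `lloyd_step()` returns a list with the new `diagram`, the
#'   `movement` (maximum seed displacement in bp) and the input seeds.
#' @examples
#' vp <- viewport("chr1", 0, 1)
#' d <- voronoi_diagram(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)), vp)
#' lloyd_step(d)$movement
#' @export
lloyd_step <- function(diagram) {
  stopifnot(inherits(diagram, "voronoi_diagram"))
  if (diagram$mode != "full") {
    abort("Lloyd smoothing applies to unreflected diagrams; rebuild with voronoi_diagram(..., smooth =, reflect =) to smooth before reflection")
  }
  step_cells(diagram, triangle = FALSE)
}

step_cells <- function(diagram, triangle) {
  old <- diagram$cells
  seeds <- tibble(x = old$centroid_x, y = old$centroid_y,
                  multiplicity = old$multiplicity)
  movement <- sqrt(max((seeds$x - old$x)^2 + (seeds$y - old$y)^2))
  cells <- build_cells(seeds, diagram$viewport, triangle = triangle)
  new <- new_voronoi_diagram(diagram$viewport, cells, mode = diagram$mode,
                             filter_distance = diagram$filter_distance)
  list(diagram = new, movement = movement, seeds = seeds)
}

#' @param iterations Number of Lloyd iterations (`>= 0`; 0 is the
#'   identity). Published figures from this approach typically use a
#'   single iteration.
#' @param tol Early-stopping tolerance on seed movement, as a fraction of
#'   the larger viewport side (default 1e-6): exact co-location of
#'   centroids and seeds is unattainable in floating point.
#' @param triangle Internal: rebuild cells constrained to the upper
#'   triangle (used when smoothing precedes reflection).
#' @rdname lloyd_step
#' @return `smooth_diagram()` returns the smoothed `voronoi_diagram`,
#'   with attributes `iterations_run` and `final_movement`.
#' @export
smooth_diagram <- function(diagram, iterations = 1, tol = 1e-6,
                           triangle = FALSE) {
  stopifnot(inherits(diagram, "voronoi_diagram"))
  if (!is.numeric(iterations) || length(iterations) != 1 ||
      is.na(iterations) || iterations < 0) {
    abort("iterations must be a single number >= 0")
  }
  vp <- diagram$viewport
  tol_bp <- tol * max(vp$end_x - vp$start_x, vp$end_y - vp$start_y)
  it <- 0
  movement <- Inf
  while (it < iterations) {
    st <- step_cells(diagram, triangle = triangle)
    diagram <- st$diagram
    movement <- st$movement
    it <- it + 1
    if (movement < tol_bp) break
  }
  attr(diagram, "iterations_run") <- it
  attr(diagram, "final_movement") <- if (is.finite(movement)) movement else 0
  diagram
}

#' Monte-Carlo quantization energy of a diagram
#'
#' The quantization energy `sum over cells of integral ||p - seed||^2 dp`
#' is the objective Lloyd's algorithm descends; it is estimated here by
#' uniform sampling over the viewport (nearest-seed assignment), mainly
#' for diagnostics and tests.
#'
#' @param diagram A `voronoi_diagram`.
#' @param n_samples Number of uniform sample points.
#' @param seed RNG seed for reproducibility.
#' @return Estimated energy in bp^4 (bp^2 area times bp^2 squared
#'   distance, divided by viewport area times n gives the mean).
#' @export
quantization_energy <- function(diagram, n_samples = 20000, seed = 1) {
  stopifnot(inherits(diagram, "voronoi_diagram"))
  vp <- diagram$viewport
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  px <- runif(n_samples, vp$start_x, vp$end_x)
  py <- runif(n_samples, vp$start_y, vp$end_y)
  lab <- nearest_seed(px, py, diagram$cells$x, diagram$cells$y)
  d2 <- (px - diagram$cells$x[lab])^2 + (py - diagram$cells$y[lab])^2
  mean(d2) * viewport_area(vp)
}
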