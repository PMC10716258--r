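#' Build a Voronoi diagram over read pairs in a viewport
#'
#' Every read pair is a 2D point; its Voronoi cell (clipped to the
#' viewport rectangle) has reciprocal area proportional to the local
#' contact density. Cells are computed exactly as the intersection of the
#' viewport with the bisector half-planes of each seed's Delaunay
#' neighbours, so cell areas partition the viewport to machine precision.
#' Coincident points are collapsed to one seed carrying a multiplicity,
#' and `density = multiplicity / area`.
#'
#' Large inputs fall back to fixed binning: when more than `max_points`
#' points survive filtering, the points are binned to `resolution` pixels
#' per axis and a `binned_density` grid is returned instead (re-querying
#' a smaller region that falls under the threshold yields a true diagram
#' again, i.e. auto-scaling resolution).
#'
#' @param points A data frame with numeric columns `x`, `y` (bp,
#'   viewport coordinates, 0-based), or a pairs tibble from
#'   [read_pairs()] which is mapped onto the viewport axes first.
#' @param viewport A [viewport()].
#' @param max_points Threshold above which fixed binning replaces the
#'   tessellation (default 100,000).
#' @param filter_distance Optional distance in bp from the diagonal
#'   `x = y`; points with perpendicular distance below it are dropped
#'   before tessellating (see [apply_filter_distance()]).
#' @param reflect Use the on-diagonal reflection trick: tessellate only
#'   the upper-triangle points constrained to the triangle and mirror the
#'   cells across `x = y` (requires a square on-diagonal viewport).
#' @param smooth Number of centroidal (Lloyd) smoothing iterations
#'   applied before any reflection (default 0 = raw diagram).
#' @param resolution Pixels per axis for the fallback grid (default 512).
#' @return A `voronoi_diagram` (fields `viewport`, `cells` tibble with
#'   `x`, `y`, `multiplicity`, `area`, `density`, `centroid_x`,
#'   `centroid_y` and a `polygon` list-column, `mode`) or a
#'   `binned_density` grid in fallback mode.
#' @examples
#' vp <- viewport("chr1", 0, 1000)
#' d <- voronoi_diagram(data.frame(x = c(100, 700), y = c(300, 900)), vp)
#' tidy(d)
#' @export
voronoi_diagram <- function(points, viewport, max_points = 1e5,
                            filter_distance = NULL, reflect = FALSE,
                            smooth = 0, resolution = 512) {
  stopifnot(inherits(viewport, "cc_viewport"))
  pts <- as_points(points, viewport)
  if (!is.null(filter_distance)) {
    pts <- apply_filter_distance(pts, filter_distance)
  }
  pts <- clip_points_to_viewport(pts, viewport)
  if (nrow(pts) > max_points) {
    return(fallback_bin(pts, viewport, resolution = resolution))
  }
  if (reflect) {
    return(reflect_upper_triangle(pts, viewport, smooth = smooth,
                                  filter_distance = filter_distance))
  }
  d <- build_voronoi(pts, viewport)
  d$filter_distance <- filter_distance
  if (smooth > 0) d <- smooth_diagram(d, iterations = smooth)
  d
}

# map pairs tibbles onto viewport axes; x/y data frames pass through
as_points <- function(points, viewport) {
  if (all(c("x", "y") %in% names(points))) {
    return(tibble(x = as.numeric(points$x), y = as.numeric(points$y)))
  }
  if (all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(points))) {
    fwd <- points$chrom1 == viewport$chrom_x & points$chrom2 == viewport$chrom_y
    out <- tibble(x = points$pos1[fwd] - 1, y = points$pos2[fwd] - 1)
    if (viewport$chrom_x != viewport$chrom_y) {
      rev <- points$chrom1 == viewport$chrom_y & points$chrom2 == viewport$chrom_x
      out <- bind_rows(out, tibble(x = points$pos2[rev] - 1,
                                   y = points$pos1[rev] - 1))
    }
    return(out)
  }
  abort("points must have columns x/y or chrom1/pos1/chrom2/pos2")
}

# closed boundaries: points exactly on the viewport edge are retained
clip_points_to_viewport <- function(pts, vp) {
  pts[pts$x >= vp$start_x & pts$x <= vp$end_x &
        pts$y >= vp$start_y & pts$y <= vp$end_y, ]
}

#' Drop points too close to the diagonal
#'
#' Removes intrachromosomal points whose perpendicular distance to the
#' `x = y` axis, `|x - y| / sqrt(2)`, is below `d` bp. For pairs tibbles
#' the criterion is `|pos2 - pos1| < d * sqrt(2)` on intrachromosomal
#' records; interchromosomal records are unaffected.
#'
#' @param points An `x`/`y` data frame or a pairs tibble.
#' @param d Minimum perpendicular distance in bp (`d >= 0`).
#' @return The filtered input.
#' @export
apply_filter_distance <- function(points, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0) {
    abort("filter distance must be a single number >= 0")
  }
  if (d == 0) return(points)
  if (all(c("x", "y") %in% names(points))) {
    return(points[abs(points$x - points$y) / sqrt(2) >= d, ])
  }
  if (all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(points))) {
    intra <- points$chrom1 == points$chrom2
    drop <- intra & abs(points$pos2 - points$pos1) < d * sqrt(2)
    return(points[!drop, ])
  }
  abort("points must have columns x/y or chrom1/pos1/chrom2/pos2")
}

# core construction: dedupe, Delaunay neighbours, exact clipped cells
build_voronoi <- function(pts, vp, triangle = FALSE) {
  seeds <- dedupe_points(pts)
  cells <- build_cells(seeds, vp, triangle = triangle)
  new_voronoi_diagram(vp, cells, mode = "full")
}

dedupe_points <- function(pts) {
  if (nrow(pts) == 0) return(tibble(x = numeric(), y = numeric(),
                                    multiplicity = integer()))
  key <- paste(pts$x, pts$y, sep = "\r")
  first <- !duplicated(key)
  tibble(x = pts$x[first], y = pts$y[first],
         multiplicity = as.integer(table(factor(key, levels = key[first]))))
}

build_cells <- function(seeds, vp, triangle = FALSE) {
  n <- nrow(seeds)
  if (n == 0) {
    abort("no points inside the viewport; widen the query region")
  }
  # translate to the viewport origin, and clip in coordinates scaled by
  # the larger side: squared raw bp magnitudes (~1e15) would otherwise
  # erode the bisector equations' precision. The triangulation itself
  # runs on the translated (unscaled) coordinates, where the sweep hull
  # is numerically happiest; the neighbour structure is scale-invariant.
  ox <- vp$start_x; oy <- vp$start_y
  sc <- max(vp$end_x - ox, vp$end_y - oy)
  tx <- seeds$x - ox; ty <- seeds$y - oy
  x <- tx / sc; y <- ty / sc
  w <- (vp$end_x - ox) / sc; h <- (vp$end_y - oy) / sc
  nb <- delaunay_neighbours(tx, ty)
  cl <- clip_voronoi_cells(x, y, nb, 0, w, 0, h, TRUE)
  polys <- cl$polygons
  area <- cl$area
  cx <- cl$centroid_x; cy <- cl$centroid_y
  if (triangle) {
    # constrain cells to the upper triangle x <= y of the square viewport
    for (i in seq_len(n)) {
      tc <- clip_poly_halfplane(polys[[i]], 1, -1, 0)
      polys[[i]] <- tc$poly
      area[i] <- tc$area
      cx[i] <- tc$cx; cy[i] <- tc$cy
    }
    keep <- area > 0
    seeds <- seeds[keep, ]; polys <- polys[keep]
    area <- area[keep]; cx <- cx[keep]; cy <- cy[keep]
  }
  polys <- lapply(polys, function(m) {
    m[, 1] <- m[, 1] * sc + ox; m[, 2] <- m[, 2] * sc + oy
    colnames(m) <- c("x", "y")
    m
  })
  area <- area * sc^2
  tibble(x = seeds$x, y = seeds$y, multiplicity = seeds$multiplicity,
         area = area, density = seeds$multiplicity / area,
         centroid_x = cx * sc + ox, centroid_y = cy * sc + oy,
         polygon = polys)
}

# Delaunay neighbour lists; degenerate (collinear / tiny) configurations
# get their exact neighbour structure directly. The sweep-hull
# triangulation is sensitive to coordinate scaling on clustered genomic
# inputs, so a failed attempt is retried on rescaled coordinates and,
# as a last resort, through deldir's construction.
delaunay_neighbours <- function(x, y) {
  n <- length(x)
  if (n == 1) return(list(integer()))
  if (n == 2) return(list(2L, 1L))
  lin <- collinear_order(x, y)
  if (!is.null(lin)) return(adjacent_neighbours(lin))
  arcs <- NULL
  for (sc in c(1, max(abs(x), abs(y), 1) / 1000, max(abs(x), abs(y), 1))) {
    tm <- tryCatch(suppressWarnings(interp::tri.mesh(x / sc, y / sc)),
                   error = function(e) e)
    if (!inherits(tm, "error")) { arcs <- tm$arcs; break }
    if (grepl("linear structure", conditionMessage(tm))) {
      return(adjacent_neighbours(collinear_order(x, y, tol = Inf)))
    }
  }
  if (is.null(arcs)) {
    if (!requireNamespace("deldir", quietly = TRUE)) {
      abort("Delaunay triangulation failed and deldir is not available as a fallback")
    }
    ds <- deldir::deldir(x, y)$delsgs
    arcs <- cbind(ds$ind1, ds$ind2)
  }
  # interp::neighbours() rescans the full arc list per node (quadratic);
  # build the adjacency directly from the arc matrix instead
  unname(split(as.integer(c(arcs[, 2], arcs[, 1])),
               factor(c(arcs[, 1], arcs[, 2]), levels = seq_len(n))))
}

# if all points lie on one line, return their order along it, else NULL
collinear_order <- function(x, y, tol = 1e-12) {
  dx <- x - x[1]; dy <- y - y[1]
  i <- which.max(dx * dx + dy * dy)
  ux <- dx[i]; uy <- dy[i]
  nrm <- sqrt(ux^2 + uy^2)
  if (nrm == 0) return(NULL)
  ux <- ux / nrm; uy <- uy / nrm
  perp <- abs(-uy * dx + ux * dy)
  span <- max(abs(dx), abs(dy))
  if (tol < Inf && any(perp > tol * max(span, 1))) return(NULL)
  order(ux * dx + uy * dy)
}

# Voronoi neighbours of collinear points are the adjacent points along
# the line (cells are bisector slabs)
adjacent_neighbours <- function(ord) {
  n <- length(ord)
  nb <- vector("list", n)
  for (k in seq_len(n)) {
    adj <- integer()
    if (k > 1) adj <- c(adj, ord[k - 1])
    if (k < n) adj <- c(adj, ord[k + 1])
    nb[[ord[k]]] <- as.integer(adj)
  }
  nb
}

# R-side single half-plane clip (a*x + b*y <= c) with area/centroid
clip_poly_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(list(poly = poly, area = 0, cx = NA_real_, cy = NA_real_))
  xs <- poly[, 1]; ys <- poly[, 2]
  f <- a * xs + b * ys - c
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (f[i] <= 0) { ox <- c(ox, xs[i]); oy <- c(oy, ys[i]) }
    if ((f[i] <= 0) != (f[j] <= 0)) {
      t <- f[i] / (f[i] - f[j])
      ox <- c(ox, xs[i] + t * (xs[j] - xs[i]))
      oy <- c(oy, ys[i] + t * (ys[j] - ys[i]))
    }
  }
  p <- cbind(x = ox, y = oy)
  a2 <- polygon_area(p)
  cen <- polygon_centroid(p, a2)
  list(poly = p, area = a2, cx = cen[1], cy = cen[2])
}

polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

polygon_centroid <- function(p, area = polygon_area(p)) {
  n <- nrow(p)
  if (n < 3 || area == 0) return(c(mean(p[, 1]), mean(p[, 2])))
  j <- c(2:n, 1)
  cross <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  c(sum((p[, 1] + p[j, 1]) * cross), sum((p[, 2] + p[j, 2]) * cross)) /
    (6 * area)
}

new_voronoi_diagram <- function(vp, cells, mode,
                                filter_distance = NULL) {
  structure(list(viewport = vp, cells = cells, mode = mode,
                 filter_distance = filter_distance),
            class = "voronoi_diagram")
}

#' @export
print.voronoi_diagram <- function(x, ...) {
  cat(sprintf("<voronoi_diagram> %d cell(s), mode '%s'\n",
              nrow(x$cells), x$mode))
  print(x$viewport)
  invisible(x)
}

#' Per-seed reciprocal-area densities
#'
#' @param diagram A `voronoi_diagram`.
#' @return A tibble `seed_x`, `seed_y`, `multiplicity`, `area`, `density`
#'   with `density = multiplicity / area` (bp^-2); the density integral
#'   `sum(density * area)` equals the number of retained read pairs.
#' @export
cell_densities <- function(diagram) {
  stopifnot(inherits(diagram, "voronoi_diagram"))
  with(diagram$cells,
       tibble(seed_x = x, seed_y = y, multiplicity = multiplicity,
              area = area, density = density))
}

#' Tessellate the upper triangle of an on-diagonal viewport and mirror it
#'
#' Intrachromosomal data are symmetric across the diagonal, so only the
#' upper-triangle points (`x <= y`) need tessellating: cells are built
#' constrained to the triangle and reflected across `x = y` to fill the
#' square. For a mirror-symmetric point set this reproduces the full
#' diagram exactly.
#'
#' @param points Upper-triangle points (others are mirrored in first).
#' @param viewport A square on-diagonal viewport.
#' @param smooth Lloyd iterations applied to the triangle diagram before
#'   reflection.
#' @inheritParams voronoi_diagram
#' @return A `voronoi_diagram` with `mode = "reflected"`; mirror cells
#'   carry `mirrored = TRUE` in the cells tibble.
#' @export
reflect_upper_triangle <- function(points, viewport, smooth = 0,
                                   filter_distance = NULL) {
  stopifnot(inherits(viewport, "cc_viewport"))
  if (!viewport_on_diagonal(viewport)) {
    abort("reflection requires a square viewport centred on the diagonal")
  }
  pts <- as_points(points, viewport)
  flip <- pts$x > pts$y
  if (any(flip)) {
    tmp <- pts$x[flip]; pts$x[flip] <- pts$y[flip]; pts$y[flip] <- tmp
  }
  pts <- clip_points_to_viewport(pts, viewport)
  if (nrow(pts) == 0) {
    abort("no points in the upper triangle; widen the query region")
  }
  d <- build_voronoi(pts, viewport, triangle = TRUE)
  if (smooth > 0) d <- smooth_diagram(d, iterations = smooth,
                                      triangle = TRUE)
  cells <- d$cells
  cells$mirrored <- FALSE
  mirror <- cells
  mirror[, c("x", "y")] <- cells[, c("y", "x")]
  mirror[, c("centroid_x", "centroid_y")] <-
    cells[, c("centroid_y", "centroid_x")]
  mirror$polygon <- lapply(cells$polygon, function(p) {
    m <- p[, c(2, 1), drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  })
  mirror$mirrored <- TRUE
  out <- new_voronoi_diagram(viewport, bind_rows(cells, mirror),
                             mode = "reflected",
                             filter_distance = filter_distance)
  out
}

#' Fixed binning fallback for very large point sets
#'
#' Above the `max_points` threshold, Voronoi cells would be smaller than
#' an output pixel, so points are binned to the output resolution
#' instead (one bin per pixel).
#'
#' @param points `x`/`y` data frame.
#' @param viewport A [viewport()].
#' @param resolution Number of pixels per axis (> 0).
#' @return A `binned_density` object: `counts` matrix (rows = x bins),
#'   `viewport`, `resolution`, `mode = "fallback_binned"`.
#' @export
fallback_bin <- function(points, viewport, resolution = 512) {
  if (!is.numeric(resolution) || resolution <= 0) {
    abort("output resolution must be > 0")
  }
  resolution <- as.integer(resolution)
  pts <- clip_points_to_viewport(as_points(points, viewport), viewport)
  ix <- bin_index(pts$x, viewport$start_x, viewport$end_x, resolution)
  iy <- bin_index(pts$y, viewport$start_y, viewport$end_y, resolution)
  counts <- matrix(0L, resolution, resolution)
  if (nrow(pts) > 0) {
    t <- table(factor(ix, levels = 1:resolution),
               factor(iy, levels = 1:resolution))
    counts <- matrix(as.integer(t), resolution, resolution)
  }
  structure(list(viewport = viewport, counts = counts,
                 resolution = resolution, mode = "fallback_binned"),
            class = "binned_density")
}

# 1-based bin index on [start, end) with the end boundary clamped inward
bin_index <- function(v, start, end, nbins) {
  i <- floor((v - start) / (end - start) * nbins) + 1L
  pmin.int(pmax.int(i, 1L), nbins)
}

#' @export
print.binned_density <- function(x, ...) {
  cat(sprintf("<binned_density> %dx%d grid, %s point(s)\n", x$resolution,
              x$resolution, format(sum(x$counts), big.mark = ",")))
  invisible(x)
}
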