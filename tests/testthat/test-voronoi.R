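test_that("degenerate and symmetric seed layouts give exact areas", {
  vp <- viewport("chr1", 0, 1)

  d1 <- voronoi_diagram(data.frame(x = 0.3, y = 0.7), vp)
  expect_equal(d1$cells$area, 1)

  corners <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  d4 <- voronoi_diagram(corners, vp)
  expect_equal(sort(d4$cells$area), rep(0.25, 4))

  # collinear points -> half-plane slabs
  dl <- voronoi_diagram(data.frame(x = c(0.1, 0.5, 0.9), y = rep(0.5, 3)), vp)
  expect_equal(sort(dl$cells$area), c(0.3, 0.3, 0.4))

  expect_error(voronoi_diagram(data.frame(x = 2, y = 2), vp), "widen")
})

test_that("four corners plus centre match the brute-force grid oracle", {
  vp <- viewport("chr1", 0, 1)
  pts <- data.frame(x = c(0, 1, 0, 1, 0.5), y = c(0, 0, 1, 1, 0.5))
  d <- voronoi_diagram(pts, vp)
  areas <- d$cells$area[match(paste(pts$x, pts$y),
                              paste(d$cells$x, d$cells$y))]
  expect_equal(areas, c(0.125, 0.125, 0.125, 0.125, 0.5), tolerance = 1e-12)

  # grid labelling oracle: areas as fractions of nearest-seed grid cells
  g <- seq(0.0005, 0.9995, by = 0.001)
  grid <- expand.grid(x = g, y = g)
  lab <- brute_nearest_chunked(grid$x, grid$y, pts$x, pts$y)
  frac <- tabulate(lab, 5) / length(lab)
  expect_equal(frac, areas, tolerance = 2e-3)
})

test_that("cell areas always sum to the viewport area", {
  vp <- viewport("chr1", 1000, 51000, "chr1", 3000, 23000)
  for (n in c(1, 2, 3, 17, 200)) {
    set.seed(n)
    d <- voronoi_diagram(
      data.frame(x = runif(n, 1000, 51000), y = runif(n, 3000, 23000)), vp)
    va <- 50000 * 20000
    expect_lt(abs(sum(d$cells$area) - va) / va, 1e-9)
  }
})

test_that("cell geometry agrees with deldir on random seed sets", {
  skip_if_not_installed("deldir")
  set.seed(31)
  x <- runif(40); y <- runif(40)
  d <- voronoi_diagram(data.frame(x = x, y = y), viewport("chr1", 0, 1))
  dd <- deldir::deldir(x, y, rw = c(0, 1, 0, 1))
  tl <- deldir::tile.list(dd)
  dd_area <- unname(vapply(tl, function(t) t$area, numeric(1)))
  ord <- match(paste(x, y), paste(d$cells$x, d$cells$y))
  expect_equal(d$cells$area[ord], dd_area, tolerance = 1e-4)
})

test_that("probe points land in the polygon of their nearest seed", {
  skip_if_not_installed("sp")
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:50, 1)
    sx <- runif(n); sy <- runif(n)
    d <- voronoi_diagram(data.frame(x = sx, y = sy), viewport("chr1", 0, 1))
    px <- runif(2000); py <- runif(2000)
    lab <- brute_nearest(px, py, sx, sy)
    ord <- match(paste(sx, sy), paste(d$cells$x, d$cells$y))
    for (i in seq_len(n)) {
      probes <- which(lab == i)
      if (length(probes) == 0) next
      poly <- d$cells$polygon[[ord[i]]]
      inside <- sp::point.in.polygon(px[probes], py[probes],
                                     poly[, 1], poly[, 2])
      expect_true(all(inside > 0))
    }
  }
})

test_that("densities integrate to the retained pair count", {
  set.seed(9)
  vp <- viewport("chr1", 0, 1e6)
  pts <- data.frame(x = runif(200, 0, 1e6), y = runif(200, 0, 1e6))
  pts <- rbind(pts, pts[1:10, ])  # coincident points -> multiplicity
  d <- voronoi_diagram(pts, vp)
  cd <- cell_densities(d)
  expect_equal(sum(cd$density * cd$area), 210, tolerance = 1e-6)
  expect_equal(sum(cd$multiplicity), 210)
  expect_equal(nrow(cd), 200)

  d1 <- voronoi_diagram(data.frame(x = 5, y = 10), viewport("chr1", 0, 1000))
  expect_equal(cell_densities(d1)$density, 1e-6)
})

test_that("filter distance keeps exactly the points far from the diagonal", {
  expect_identical(apply_filter_distance(data.frame(x = 1:3, y = 3:1), 0),
                   data.frame(x = 1:3, y = 3:1))
  expect_equal(nrow(apply_filter_distance(data.frame(x = 100, y = 100), 1)), 0)
  expect_error(apply_filter_distance(data.frame(x = 1, y = 1), -1), ">= 0")

  set.seed(4)
  pts <- data.frame(x = runif(500, 0, 1e5), y = runif(500, 0, 1e5))
  kept <- apply_filter_distance(pts, 1000)
  expect_identical(kept, pts[abs(pts$x - pts$y) >= 1000 * sqrt(2), ])

  # pairs form: interchromosomal records unaffected
  pr <- tibble::tibble(chrom1 = c("chr1", "chr1"), pos1 = c(100, 100),
                       chrom2 = c("chr1", "chr2"), pos2 = c(150, 150))
  expect_equal(apply_filter_distance(pr, 1000)$chrom2, "chr2")
})

test_that("reflection reproduces the full diagram on symmetric input", {
  set.seed(21)
  vp <- viewport("chr1", 0, 1000)
  up <- data.frame(x = runif(30, 0, 1000), y = runif(30, 0, 1000))
  up <- up[up$x < up$y, ]
  refl <- reflect_upper_triangle(up, vp)
  expect_equal(refl$mode, "reflected")
  expect_equal(sum(refl$cells$area), 1e6, tolerance = 1e-9)

  full <- voronoi_diagram(rbind(up, data.frame(x = up$y, y = up$x)), vp)
  key <- function(d) paste(round(d$cells$x, 9), round(d$cells$y, 9))
  ord <- match(key(full), key(refl))
  expect_false(anyNA(ord))
  expect_equal(refl$cells$area[ord], full$cells$area, tolerance = 1e-9)

  # single off-diagonal point: two mirror cells of equal area
  one <- reflect_upper_triangle(data.frame(x = 200, y = 700), vp)
  expect_equal(nrow(one$cells), 2)
  expect_equal(one$cells$area[1], one$cells$area[2], tolerance = 1e-12)

  expect_error(reflect_upper_triangle(data.frame(x = 900, y = 100)[0, ], vp),
               "widen")
  expect_error(
    reflect_upper_triangle(data.frame(x = 1, y = 2),
                           viewport("chr1", 0, 1000, "chr1", 0, 2000)),
    "square")
})

test_that("fallback binning triggers above the threshold and conserves counts", {
  vp <- viewport("chr1", 0, 1000)
  set.seed(2)
  pts <- data.frame(x = runif(101, 0, 1000), y = runif(101, 0, 1000))
  fb <- voronoi_diagram(pts, vp, max_points = 100, resolution = 10)
  expect_s3_class(fb, "binned_density")
  expect_equal(fb$mode, "fallback_binned")
  expect_equal(sum(fb$counts), 101)

  # at the threshold exactly, a true diagram is returned
  expect_s3_class(voronoi_diagram(pts[1:100, ], vp, max_points = 100),
                  "voronoi_diagram")
  # the documented default threshold is 100,000 points
  expect_equal(formals(voronoi_diagram)$max_points, 1e5)

  # zooming into a sparse sub-viewport returns a true diagram
  sub <- viewport("chr1", 0, 100)
  inside <- pts[pts$x <= 100 & pts$y <= 100, ]
  expect_s3_class(voronoi_diagram(pts, sub, max_points = 100),
                  "voronoi_diagram")
  expect_error(fallback_bin(pts, vp, resolution = 0), "> 0")
})

test_that("construction is deterministic for identical input", {
  set.seed(77)
  pts <- data.frame(x = runif(300), y = runif(300))
  vp <- viewport("chr1", 0, 1)
  d1 <- voronoi_diagram(pts, vp)
  d2 <- voronoi_diagram(pts, vp)
  expect_identical(d1$cells$area, d2$cells$area)
  expect_identical(d1$cells$polygon, d2$cells$polygon)
})
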