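all_bins <- function(nb, f, chrom = "chrT") {
  g <- expand.grid(bin_x = 0:(nb - 1), bin_y = 0:(nb - 1))
  g <- g[g$bin_x <= g$bin_y, ]
  out <- tibble::tibble(chrom = chrom, bin_x = g$bin_x, bin_y = g$bin_y,
                        count = f(g$bin_y - g$bin_x))
  attr(out, "bin_size") <- 5000
  out
}

test_that("the expected model recovers constant and deterministic decay fields", {
  nb <- 60
  cs <- tibble::tibble(name = "chrT", length = nb * 5000)

  ec <- expected_by_distance(all_bins(nb, function(d) rep(3, length(d))),
                             chrom_sizes = cs)
  expect_equal(ec$expected, rep(3, nb))

  f <- function(d) 100 / (d + 1)
  ef <- expected_by_distance(all_bins(nb, f), chrom_sizes = cs)
  expect_equal(ef$expected, f(0:(nb - 1)), tolerance = 1e-12)

  # conservation: sum over offsets of expected * bins-at-offset = total pairs
  counts <- all_bins(nb, function(d) rpois(length(d), 5))
  e <- expected_by_distance(counts, chrom_sizes = cs)
  expect_equal(sum(e$expected * (nb - e$offset)), sum(counts$count))

  expect_error(expected_by_distance(counts[0, ]), "no intrachromosomal")
})

test_that("expected tracks a known decay under Poisson noise", {
  set.seed(19)
  nb <- 300
  f <- function(d) 50 / (d + 5)
  counts <- all_bins(nb, function(d) rpois(length(d), f(d)))
  cs <- tibble::tibble(name = "chrT", length = nb * 5000)
  e <- expected_by_distance(counts, chrom_sizes = cs)
  n_at <- nb - e$offset
  se <- sqrt(f(e$offset) / n_at)
  ok <- abs(e$expected - f(e$offset)) <= 3 * se
  expect_gt(mean(ok), 0.98)  # ~99.7% expected within 3 SE
})

test_that("pileups are exact observed/expected ratio windows", {
  nb <- 200
  f <- function(d) 100 / (d + 1)
  counts <- all_bins(nb, f)
  cs <- tibble::tibble(name = "chrT", length = nb * 5000)
  exp_model <- expected_by_distance(counts, chrom_sizes = cs)
  loop <- tibble::tibble(chrom = "chrT", bin_x = 60, bin_y = 100)

  m <- pileup_at(loop, counts, exp_model)
  expect_equal(dim(m), c(21, 21))
  expect_equal(unclass(m), matrix(1, 21, 21), ignore_attr = TRUE)

  # doubling only the centre bin (against a fixed expected model)
  counts2 <- counts
  hit <- counts2$bin_x == 60 & counts2$bin_y == 100
  counts2$count[hit] <- 2 * counts2$count[hit]
  m2 <- pileup_at(loop, counts2, exp_model)
  expect_equal(m2[11, 11], 2)
  expect_equal(sum(abs(unclass(m2) - 1) > 1e-9), 1)

  # edge/diagonal exclusion
  expect_warning(res <- pileup_at(tibble::tibble(chrom = "chrT", bin_x = 3,
                                                 bin_y = 100),
                                  counts, exp_model), "excluded")
  expect_null(res)
  expect_warning(pileup_at(tibble::tibble(chrom = "chrT", bin_x = 60,
                                          bin_y = 65), counts, exp_model),
                 "excluded")

  # zero expected at an in-window offset -> missing pixel
  ez <- expected_model(tibble::tibble(chrom = "chrT", offset = 0:(nb - 1),
                                      expected = c(rep(1, 35), 0,
                                                   rep(1, nb - 36))),
                       bin_size = 5000, n_bins = c(chrT = nb))
  mz <- pileup_at(loop, counts, ez)
  expect_true(anyNA(unclass(mz)))
})

test_that("signal enrichment follows its block definition", {
  expect_equal(signal_enrichment(matrix(1, 21, 21)), 1)

  m <- matrix(7, 21, 21)   # arbitrary elsewhere
  m[10:12, 10:12] <- 4
  for (b in list(c(1, 1), c(1, 10), c(1, 19), c(10, 19), c(19, 19))) {
    m[b[1]:(b[1] + 2), b[2]:(b[2] + 2)] <- 2
  }
  m[10:12, 10:12] <- 4  # centre block overwrites the middle column strips
  expect_equal(signal_enrichment(m), 2)

  mz <- m
  for (b in list(c(1, 1), c(1, 10), c(1, 19), c(10, 19), c(19, 19))) {
    mz[b[1]:(b[1] + 2), b[2]:(b[2] + 2)] <- 0
  }
  mz[10:12, 10:12] <- 4
  expect_identical(signal_enrichment(mz), Inf)

  # scale invariance
  set.seed(23)
  r <- matrix(rexp(441), 21, 21)
  expect_equal(signal_enrichment(r * 17), signal_enrichment(r))

  expect_error(signal_enrichment(matrix(1, 20, 21)), "21 x 21")
})

test_that("centre and background blocks sit where the definition puts them", {
  b <- vorocc:::enrichment_blocks()
  expect_equal(b$center, list(rows = 10:12, cols = 10:12))
  expect_equal(b$background$upper_left, list(rows = 1:3, cols = 1:3))
  expect_equal(b$background$upper_middle, list(rows = 1:3, cols = 10:12))
  expect_equal(b$background$upper_right, list(rows = 1:3, cols = 19:21))
  expect_equal(b$background$middle_right, list(rows = 10:12, cols = 19:21))
  expect_equal(b$background$lower_right, list(rows = 19:21, cols = 19:21))
})

test_that("aggregation averages finite enrichments and drops infinite ones", {
  nb <- 200
  f <- function(d) 100 / (d + 1)
  counts <- all_bins(nb, f)
  cs <- tibble::tibble(name = "chrT", length = nb * 5000)
  exp_model <- expected_by_distance(counts, chrom_sizes = cs)

  counts2 <- counts
  hit <- counts2$bin_x == 60 & counts2$bin_y == 100
  counts2$count[hit] <- 2 * counts2$count[hit]
  loops <- tibble::tibble(chrom = "chrT", bin_x = c(60, 80), bin_y = c(100, 140))
  agg <- aggregate_enrichment(loops, counts2, exp_model)
  expect_equal(agg$n_finite, 2)
  expect_gt(agg$mean_enrichment, 1)
  expect_equal(dim(agg$mean_matrix), c(21, 21))

  # a zero-background loop is excluded from the average
  counts3 <- counts
  win <- counts3$bin_x >= 50 & counts3$bin_x <= 70 &
    counts3$bin_y >= 90 & counts3$bin_y <= 110
  counts3$count[win] <- 0
  counts3$count[counts3$bin_x == 60 & counts3$bin_y == 100] <- 5
  agg2 <- aggregate_enrichment(loops, counts3, exp_model)
  expect_equal(agg2$n_finite, 1)
  expect_true(is.infinite(agg2$enrichments$enrichment[1]))
})

test_that("pileup of loop-free translational data has enrichment near one", {
  set.seed(29)
  sim <- simulate_pairs(sim_spec(chrom = "chrB", chrom_length = 2e7,
                                 n_pairs = 40000, alpha = 1, seed = 29))
  counts <- bin_counts(sim$pairs)
  cs <- tibble::tibble(name = "chrB", length = 2e7)
  e <- expected_by_distance(counts, chrom_sizes = cs)
  set.seed(30)
  bx <- sample(100:3800, 200)
  loops <- tibble::tibble(chrom = "chrB", bin_x = bx,
                          bin_y = bx + sample(12:60, 200, replace = TRUE))
  agg <- suppressWarnings(aggregate_enrichment(loops, counts, e))
  expect_gt(agg$n_finite, 100)
  # the aggregate (mean-matrix) enrichment is the bias-free summary
  expect_equal(signal_enrichment(agg$mean_matrix), 1, tolerance = 0.25)
})
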