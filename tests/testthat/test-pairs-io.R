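test_that("toy pairs files parse in file order and filter by region", {
  f <- write_toy_pairs(c("r1\tchr1\t100\tchr1\t900\t+\t-",
                         "r2\tchr1\t200\tchr2\t50\t+\t+"))
  p <- read_pairs(f)
  expect_equal(p$read_id, c("r1", "r2"))
  expect_equal(p$pos1, c(100, 200))
  expect_equal(attr(p, "chromsizes")$name, c("chr1", "chr2"))

  q <- read_pairs(f, "chr1:1-500", "chr1:501-1000")
  expect_equal(q$read_id, "r1")

  expect_warning(empty <- read_pairs(f, "chrZ:1-100", "chrZ:1-100"),
                 "chrZ")
  expect_equal(nrow(empty), 0)
})

test_that("header and record validation raise informative errors", {
  bad <- tempfile()
  writeLines(c("#not a pairs header", "r1\tchr1\t1\tchr1\t2\t+\t-"), bad)
  expect_error(read_pairs(bad), "pairs format")

  f <- write_toy_pairs(c("r1\tchr1\t100\tchr1\t900\t+\t-",
                         "r2\tchr1\tfoo\tchr1\t5\t+\t-"))
  expect_error(read_pairs(f), "line 5")

  f2 <- write_toy_pairs("r1\tchr1\t100\tchr1")
  expect_error(read_pairs(f2), ">= 7")
})

test_that("parsing is loss-free for canonical input", {
  body <- c("r1\tchr1\t100\tchr1\t900\t+\t-",
            "r2\tchr1\t200\tchr2\t50\t+\t+\tpayload\tmore")
  f <- write_toy_pairs(body)
  p <- read_pairs(f)
  expect_identical(vorocc:::serialize_pairs_body(p), body)
})

test_that("upper-triangle normalization follows header chromosome order", {
  f <- write_toy_pairs(c("r1\tchr2\t10\tchr1\t700\t+\t-",
                         "r2\tchr1\t900\tchr1\t100\t+\t-"))
  p <- normalize_pairs(read_pairs(f), chrom_order = c("chr1", "chr2"))
  expect_equal(p$chrom1, c("chr1", "chr1"))
  expect_equal(p$pos1, c(700, 100))
  expect_equal(p$strand1, c("-", "-"))
  expect_equal(p$pos2, c(10, 900))
})

test_that("indexed region queries equal linear scans on random regions", {
  sim <- simulate_pairs(sim_spec(chrom = "chrA", chrom_length = 2e6,
                                 n_pairs = 5000, seed = 7))
  f <- tempfile(fileext = ".pairs")
  write_pairs(sim$pairs, f)
  idx <- build_pairs_index(f, tile_size = 1e5)
  ixp <- tempfile(fileext = ".json")
  write_pairs_index(idx, ixp)
  idx2 <- read_pairs_index(ixp)

  set.seed(42)
  for (k in 1:20) {
    a0 <- sort(sample(2e6, 2))
    b0 <- sort(sample(2e6, 2))
    ra <- sprintf("chrA:%d-%d", a0[1], a0[2])
    rb <- sprintf("chrA:%d-%d", b0[1], b0[2])
    strip <- function(d) {
      d <- as.data.frame(d)
      attributes(d) <- attributes(d)[c("names", "class", "row.names")]
      rownames(d) <- NULL
      d
    }
    lin <- read_pairs(f, ra, rb)
    via_idx <- read_pairs(f, ra, rb, index = idx2)
    expect_identical(strip(lin[order(lin$read_id), names(via_idx)]),
                     strip(via_idx[order(via_idx$read_id), ]))
  }
})

test_that("index construction validates sorting and handles empty bodies", {
  f <- write_toy_pairs(character())
  idx <- build_pairs_index(f)
  expect_equal(nrow(idx$chromosomes), 2)
  expect_equal(nrow(idx$blocks), 0)

  bad <- write_toy_pairs(c("r1\tchr1\t500\tchr1\t900\t+\t-",
                           "r2\tchr1\t100\tchr1\t900\t+\t-"))
  expect_error(build_pairs_index(bad), "line 5")
  expect_s3_class(build_pairs_index(bad, sorted = FALSE), "cc_pairs_index")
})

test_that("BGZF and plain-text readers yield identical record streams", {
  skip_if_not_installed("Rsamtools")
  sim <- simulate_pairs(sim_spec(chrom = "chrA", chrom_length = 1e6,
                                 n_pairs = 800, seed = 5))
  f <- tempfile(fileext = ".pairs")
  write_pairs(sim$pairs, f)
  bg <- Rsamtools::bgzip(f, dest = paste0(f, ".gz"))
  expect_identical(as.data.frame(read_pairs(f)),
                   as.data.frame(read_pairs(bg)))
  # indexed access through the BGZF file too (uncompressed offsets)
  idx <- build_pairs_index(bg, tile_size = 5e4)
  q <- read_pairs(bg, "chrA:100001-300000", "chrA:300001-900000", index = idx)
  lin <- read_pairs(f, "chrA:100001-300000", "chrA:300001-900000")
  expect_setequal(q$read_id, lin$read_id)
})

test_that("interact records round trip exactly in both layouts", {
  rec <- tibble::tibble(source_chrom = "chr1", source_start = 3170000,
                        source_end = 3175000, target_chrom = "chr1",
                        target_start = 4260000, target_end = 4265000,
                        score = 5, name = "contact1")
  for (compact in c(FALSE, TRUE)) {
    f <- tempfile(fileext = ".interact")
    write_interact(rec, f, compact = compact)
    expect_identical(as.data.frame(read_interact(f)), as.data.frame(rec))
  }

  f0 <- tempfile()
  write_interact(rec[0, ], f0)
  expect_equal(nrow(read_interact(f0)), 0)

  bad <- rec
  bad$source_end <- bad$source_start
  expect_error(write_interact(bad, tempfile()), "start must be < end")
})

test_that("loop caller output survives an interact round trip", {
  sim <- small_planted_sim()
  loops <- suppressWarnings(call_loops(sim$pairs))
  f <- tempfile(fileext = ".interact")
  write_loops(loops, f, format = "interact")
  back <- read_interact(f)
  expect_equal(nrow(back), nrow(loops))
  expect_equal(back$source_start, loops$bin_x * 5000)
  expect_equal(back$target_start, loops$bin_y * 5000)
  expect_equal(back$score, as.numeric(loops$support))

  ft <- tempfile(fileext = ".tsv")
  write_loops(loops, ft, format = "tsv")
  back2 <- read_loops(ft)
  expect_equal(as.data.frame(back2), as.data.frame(loops), tolerance = 1e-12)
})
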