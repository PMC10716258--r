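# shared test helpers: tiny pairs files, brute-force geometry oracles

write_toy_pairs <- function(records, path = tempfile(fileext = ".pairs"),
                            chromsizes = c(chr1 = 1000, chr2 = 1000)) {
  header <- c("## pairs format v1.0",
              sprintf("#chromsize: %s %d", names(chromsizes), chromsizes))
  writeLines(c(header, records), path)
  path
}

# independent nearest-seed labelling (ties -> lowest seed index), pure R
brute_nearest <- function(px, py, sx, sy) {
  vapply(seq_along(px), function(i) {
    which.min((px[i] - sx)^2 + (py[i] - sy)^2)
  }, integer(1))
}

# chunked version for large probe sets
brute_nearest_chunked <- function(px, py, sx, sy, chunk = 50000) {
  out <- integer(length(px))
  for (s in seq(1, length(px), by = chunk)) {
    e <- min(s + chunk - 1, length(px))
    d2 <- outer(px[s:e], sx, `-`)^2 + outer(py[s:e], sy, `-`)^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

random_diagram <- function(n, seed, vp = viewport("chr1", 0, 1)) {
  set.seed(seed)
  voronoi_diagram(data.frame(x = runif(n, vp$start_x, vp$end_x),
                             y = runif(n, vp$start_y, vp$end_y)), vp)
}

# simulated pairs reused by caller/pileup tests
small_planted_sim <- function(seed = 11, n_pairs = 20000, n_loops = 8,
                              chrom_length = 2e7) {
  base <- round(seq(2e6, 14e6, length.out = n_loops) / 5000) * 5000
  anchors <- tibble::tibble(
    pos1 = base + 2500,
    pos2 = base + 2500 + round(seq(1e5, 8e5, length.out = n_loops) / 5000) * 5000,
    n_pairs = 15, jitter_sd = 300)
  simulate_pairs(sim_spec(chrom = "chrS", chrom_length = chrom_length,
                          n_pairs = n_pairs, alpha = 1,
                          loops = anchors, seed = seed))
}
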