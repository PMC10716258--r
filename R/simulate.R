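#' Specify a synthetic pairs-data simulation
#'
#' Describes a single synthetic chromosome: background read pairs whose
#' genomic distance follows a truncated power law (P(s) proportional to
#' s^-alpha on `min_distance .. chrom_length`), optional TAD blocks that
#' multiply the within-block contact frequency, and planted focal loops
#' (extra pairs around an anchor point with Gaussian positional jitter).
#' Identical spec + seed reproduces the output exactly.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Length in bp.
#' @param n_pairs Number of background pairs.
#' @param alpha Distance-decay exponent (> 0, default 1).
#' @param min_distance Smallest sampled distance in bp (default 1000,
#'   mirroring the caller's minimum-distance default).
#' @param tads Optional tibble `start`, `end`, `multiplier` (bp,
#'   0-based half-open; multiplier >= 1 applies to pairs with both ends
#'   inside the same block).
#' @param loops Optional tibble `pos1`, `pos2`, `n_pairs`, `jitter_sd`
#'   (anchor coordinates in bp, 1-based; extra pair count; jitter SD in
#'   bp, >= 0).
#' @param seed RNG seed.
#' @return A `cc_sim_spec`.
#' @export
sim_spec <- function(chrom = "chrS", chrom_length = 5e7, n_pairs = 50000,
                     alpha = 1, min_distance = 1000, tads = NULL,
                     loops = NULL, seed = 1) {
  if (alpha <= 0) abort("alpha must be > 0")
  if (min_distance < 1 || min_distance >= chrom_length) {
    abort("min_distance must lie in [1, chrom_length)")
  }
  if (!is.null(loops) && nrow(loops) > 0) {
    if (!all(c("pos1", "pos2", "n_pairs", "jitter_sd") %in% names(loops))) {
      abort("loops needs columns pos1, pos2, n_pairs, jitter_sd")
    }
    if (any(loops$pos1 < 1 | loops$pos2 < 1 |
            loops$pos1 > chrom_length | loops$pos2 > chrom_length)) {
      abort("loop anchors must lie inside the chromosome")
    }
    if (any(loops$jitter_sd < 0)) abort("jitter_sd must be >= 0")
  }
  if (!is.null(tads) && nrow(tads) > 0) {
    stopifnot(all(c("start", "end", "multiplier") %in% names(tads)),
              all(tads$end > tads$start), all(tads$multiplier >= 1))
  }
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 n_pairs = n_pairs, alpha = alpha,
                 min_distance = min_distance,
                 tads = tads, loops = loops, seed = seed),
            class = "cc_sim_spec")
}

# inverse-CDF sample of the truncated power law on [dmin, L]
sample_powerlaw <- function(n, alpha, dmin, L) {
  u <- runif(n)
  s <- if (abs(alpha - 1) < 1e-12) {
    dmin * (L / dmin)^u
  } else {
    (dmin^(1 - alpha) + u * (L^(1 - alpha) - dmin^(1 - alpha)))^(1 / (1 - alpha))
  }
  pmin(pmax(round(s), dmin), L - 1)
}

#' Generate a synthetic pairs data set with planted structure
#'
#' Background pairs are drawn by sampling a distance from the truncated
#' power law (inverse CDF) and a uniform midpoint; TAD multipliers are
#' applied by rejection (pairs with both ends in a block are `m` times
#' as likely to be kept); loop pairs are the anchor plus Gaussian jitter
#' on each side. The result is upper-triangle normalized and sorted by
#' position, as a valid pairs file with a `#chromsize` header.
#'
#' @param spec A [sim_spec()].
#' @param path Optional output path (`.pairs` or `.pairs.gz`); when
#'   given, the file is written.
#' @return A `cc_sim` list: `pairs` (tibble), `truth` (tibble
#'   `loop_id`, `pos1`, `pos2`, `bin_x`, `bin_y`, `n_pairs` on the
#'   0-anchored 5 kb grid), `spec`, and `path` when written.
#' @examples
#' sim <- simulate_pairs(sim_spec(chrom_length = 1e6, n_pairs = 100))
#' nrow(sim$pairs)
#' @export
simulate_pairs <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "cc_sim_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  L <- spec$chrom_length
  draw_background <- function(n) {
    s <- sample_powerlaw(n, spec$alpha, spec$min_distance, L)
    m <- runif(n, s / 2, L - s / 2)
    p1 <- pmax(1, round(m - s / 2))
    p2 <- p1 + s
    keep <- p2 <= L
    tibble(pos1 = p1[keep], pos2 = p2[keep])
  }
  tad_weight <- function(p1, p2) {
    w <- rep(1, length(p1))
    if (!is.null(spec$tads) && nrow(spec$tads) > 0) {
      for (i in seq_len(nrow(spec$tads))) {
        inside <- p1 - 1 >= spec$tads$start[i] & p1 - 1 < spec$tads$end[i] &
          p2 - 1 >= spec$tads$start[i] & p2 - 1 < spec$tads$end[i]
        w[inside] <- w[inside] * spec$tads$multiplier[i]
      }
    }
    w
  }
  max_w <- if (!is.null(spec$tads) && nrow(spec$tads) > 0) {
    prod(pmax(spec$tads$multiplier, 1))
  } else 1
  bg <- tibble(pos1 = numeric(), pos2 = numeric())
  while (nrow(bg) < spec$n_pairs) {
    cand <- draw_background(max(spec$n_pairs, 1000))
    acc <- runif(nrow(cand)) < tad_weight(cand$pos1, cand$pos2) / max_w
    bg <- bind_rows(bg, cand[acc, ])
  }
  bg <- bg[seq_len(spec$n_pairs), ]

  truth <- tibble(loop_id = integer(), pos1 = numeric(), pos2 = numeric(),
                  bin_x = numeric(), bin_y = numeric(), n_pairs = integer())
  lp <- tibble(pos1 = numeric(), pos2 = numeric())
  if (!is.null(spec$loops) && nrow(spec$loops) > 0) {
    for (i in seq_len(nrow(spec$loops))) {
      lo <- spec$loops[i, ]
      need <- lo$n_pairs
      got <- tibble(pos1 = numeric(), pos2 = numeric())
      while (nrow(got) < need) {
        p1 <- round(lo$pos1 + rnorm(need, 0, lo$jitter_sd))
        p2 <- round(lo$pos2 + rnorm(need, 0, lo$jitter_sd))
        ok <- p1 >= 1 & p1 <= L & p2 >= 1 & p2 <= L
        got <- bind_rows(got, tibble(pos1 = p1[ok], pos2 = p2[ok]))
      }
      got <- got[seq_len(need), ]
      lp <- bind_rows(lp, got)
      truth <- bind_rows(truth, tibble(
        loop_id = i, pos1 = lo$pos1, pos2 = lo$pos2,
        bin_x = floor((lo$pos1 - 1) / 5000),
        bin_y = floor((lo$pos2 - 1) / 5000), n_pairs = as.integer(need)))
    }
  }
  all <- bind_rows(bg, lp)
  swap <- all$pos2 < all$pos1
  tmp <- all$pos1[swap]; all$pos1[swap] <- all$pos2[swap]
  all$pos2[swap] <- tmp
  all <- arrange(all, .data$pos1, .data$pos2)
  pairs <- tibble(read_id = sprintf("sim%07d", seq_len(nrow(all))),
                  chrom1 = spec$chrom, pos1 = all$pos1,
                  chrom2 = spec$chrom, pos2 = all$pos2,
                  strand1 = "+", strand2 = "-", extra = NA_character_)
  chromsizes <- tibble(name = spec$chrom, length = L)
  attr(pairs, "chromsizes") <- chromsizes
  out <- structure(list(pairs = pairs, truth = truth, spec = spec),
                   class = "cc_sim")
  if (!is.null(path)) {
    write_pairs(pairs, path, chromsizes = chromsizes)
    out$path <- path
  }
  out
}

#' @export
print.cc_sim <- function(x, ...) {
  cat(sprintf("<simulated pairs> %s records on %s (%d planted loop(s))\n",
              format(nrow(x$pairs), big.mark = ","), x$spec$chrom,
              nrow(x$truth)))
  invisible(x)
}

#' Evaluate called loop bins against the simulation truth
#'
#' Recall is the fraction of truth bins called exactly; the precision
#' proxy is the fraction of called bins within one bin (Chebyshev
#' distance) of a truth bin. With no called bins the precision proxy is
#' undefined and reported as 1.0 with `zero_support = TRUE`.
#'
#' @param called Loop-bin tibble from [call_loops()].
#' @param truth Truth tibble from [simulate_pairs()] (columns `bin_x`,
#'   `bin_y`).
#' @return A one-row tibble `recall`, `precision`, `n_called`,
#'   `n_truth`, `zero_support`.
#' @export
truth_eval <- function(called, truth) {
  n_truth <- nrow(truth)
  n_called <- nrow(called)
  recall <- if (n_truth == 0) NA_real_ else {
    mean(paste(truth$bin_x, truth$bin_y) %in%
           paste(called$bin_x, called$bin_y))
  }
  if (n_called == 0) {
    return(tibble(recall = if (n_truth == 0) NA_real_ else recall,
                  precision = 1.0, n_called = 0L, n_truth = n_truth,
                  zero_support = TRUE))
  }
  near <- vapply(seq_len(n_called), function(i) {
    any(abs(called$bin_x[i] - truth$bin_x) <= 1 &
          abs(called$bin_y[i] - truth$bin_y) <= 1)
  }, logical(1))
  tibble(recall = recall, precision = mean(near),
         n_called = as.integer(n_called), n_truth = as.integer(n_truth),
         zero_support = FALSE)
}
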