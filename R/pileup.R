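#' Bin intrachromosomal pairs into a sparse contact-count table
#'
#' Upper-triangle counts per `bin_size` square bin (grid anchored at
#' coordinate 0), one row per non-empty bin.
#'
#' @param pairs Pairs tibble.
#' @param bin_size Bin side in bp (default 5000).
#' @return A tibble `chrom`, `bin_x`, `bin_y`, `count` (with
#'   `bin_x <= bin_y`), attribute `bin_size`.
#' @export
bin_counts <- function(pairs, bin_size = 5000) {
  intra <- pairs[pairs$chrom1 == pairs$chrom2, ]
  bx <- floor((pmin(intra$pos1, intra$pos2) - 1) / bin_size)
  by <- floor((pmax(intra$pos1, intra$pos2) - 1) / bin_size)
  out <- tibble(chrom = intra$chrom1, bin_x = bx, bin_y = by) |>
    count(.data$chrom, .data$bin_x, .data$bin_y, name = "count")
  attr(out, "bin_size") <- bin_size
  out
}

#' Expected contact count per bin as a function of diagonal offset
#'
#' The distance-decay expected model: for each chromosome and each
#' diagonal offset `d` (in bins), the mean observed count over all
#' upper-triangle bins at that offset (a chromosome of `n_bins` bins has
#' `n_bins - d` of them, zeros included). By construction
#' `sum_d expected(d) * (n_bins - d)` equals the total pair count, and
#' `observed / expected` ratios are what pileups average.
#'
#' @param pairs Pairs tibble (or a [bin_counts()] result).
#' @param chrom_sizes Tibble `name`,`length`; defaults to the
#'   `chromsizes` attribute, else lengths are inferred from the data.
#' @param bin_size Bin side in bp (default 5000).
#' @return A `cc_expected` object: tibble `chrom`, `offset`, `expected`
#'   covering every offset `0 .. n_bins - 1`, attributes `bin_size` and
#'   `n_bins` (named per chromosome).
#' @export
expected_by_distance <- function(pairs, chrom_sizes = attr(pairs, "chromsizes"),
                                 bin_size = 5000) {
  counts <- if (all(c("bin_x", "bin_y", "count") %in% names(pairs))) {
    pairs
  } else {
    bin_counts(pairs, bin_size = bin_size)
  }
  if (nrow(counts) == 0) abort("no intrachromosomal pairs to model")
  chroms <- unique(counts$chrom)
  n_bins <- vapply(chroms, function(ch) {
    len <- if (!is.null(chrom_sizes) && ch %in% chrom_sizes$name) {
      chrom_sizes$length[match(ch, chrom_sizes$name)]
    } else {
      (max(counts$bin_y[counts$chrom == ch]) + 1) * bin_size
    }
    ceiling(len / bin_size)
  }, numeric(1))
  names(n_bins) <- chroms
  out <- bind_rows(lapply(chroms, function(ch) {
    nb <- n_bins[[ch]]
    sub <- counts[counts$chrom == ch, ]
    off <- sub$bin_y - sub$bin_x
    sums <- vapply(split(sub$count, factor(off, levels = 0:(nb - 1))),
                   sum, numeric(1))
    tibble(chrom = ch, offset = 0:(nb - 1),
           expected = unname(sums) / (nb - 0:(nb - 1)))
  }))
  structure(out, bin_size = bin_size, n_bins = n_bins,
            class = c("cc_expected", class(out)))
}

#' Construct an expected model from a table of per-offset means
#'
#' Useful for supplying an externally computed expected track.
#'
#' @param table Tibble `chrom`, `offset`, `expected`.
#' @param bin_size Bin side in bp.
#' @param n_bins Named numeric vector: bins per chromosome.
#' @return A `cc_expected` object.
#' @export
expected_model <- function(table, bin_size, n_bins) {
  stopifnot(all(c("chrom", "offset", "expected") %in% names(table)),
            all(table$expected >= 0), !is.null(names(n_bins)))
  structure(as_tibble(table), bin_size = bin_size, n_bins = n_bins,
            class = c("cc_expected", class(as_tibble(table))))
}

expected_lookup <- function(expected, chrom, offsets) {
  sub <- expected[expected$chrom == chrom, ]
  e <- sub$expected[match(offsets, sub$offset)]
  e[is.na(e)] <- 0
  e
}

#' Observed/expected pileup matrix around one candidate loop bin
#'
#' Extracts the (2*flank+1) x (2*flank+1) window of observed counts
#' centred on the loop bin (default flank 10 bins = 50 kb, a 21 x 21
#' matrix with the loop at centre (11, 11) in 1-based coordinates) and
#' divides each pixel by the expected count at its diagonal offset.
#' The count table is symmetric, so window pixels below the diagonal
#' read the mirrored bin and `expected(|offset|)`. Pixels whose expected
#' value is zero are recorded as missing (`NA`).
#'
#' @param loop One loop-bin row (`chrom`, `bin_x`, `bin_y`).
#' @param counts Sparse count tibble from [bin_counts()].
#' @param expected A `cc_expected` model.
#' @param flank Window half-width in bins (default 10).
#' @return A `cc_pileup` matrix of observed/expected ratios, or `NULL`
#'   with a warning when the loop sits closer than `flank` bins to the
#'   matrix edge or the diagonal.
#' @export
pileup_at <- function(loop, counts, expected, flank = 10) {
  stopifnot(inherits(expected, "cc_expected"))
  ch <- loop$chrom
  nb <- attr(expected, "n_bins")[[ch]]
  if (is.null(nb)) abort(sprintf("chromosome %s absent from expected model", ch))
  bx <- loop$bin_x; by <- loop$bin_y
  if (bx - flank < 0 || by + flank > nb - 1 || bx + flank > nb - 1 ||
      by - flank < 0 || (by - bx) < flank) {
    warn(sprintf(
      "loop bin (%s, %d, %d) closer than %d bins to the matrix edge or diagonal; excluded",
      ch, bx, by, flank))
    return(NULL)
  }
  ii <- (bx - flank):(bx + flank)
  jj <- (by - flank):(by + flank)
  sub <- counts[counts$chrom == ch, ]
  grid <- expand.grid(i = ii, j = jj)
  lo <- pmin(grid$i, grid$j); hi <- pmax(grid$i, grid$j)
  obs <- sub$count[match(paste(lo, hi), paste(sub$bin_x, sub$bin_y))]
  obs[is.na(obs)] <- 0
  e <- expected_lookup(expected, ch, abs(grid$j - grid$i))
  ratio <- ifelse(e > 0, obs / e, NA_real_)
  m <- matrix(ratio, nrow = 2 * flank + 1, ncol = 2 * flank + 1)
  structure(m, class = c("cc_pileup", "matrix"), loop = loop)
}

# 1-based inclusive pixel blocks of the 21x21 enrichment definition
enrichment_blocks <- function() {
  list(center = list(rows = 10:12, cols = 10:12),
       background = list(
         upper_left = list(rows = 1:3, cols = 1:3),
         upper_middle = list(rows = 1:3, cols = 10:12),
         upper_right = list(rows = 1:3, cols = 19:21),
         middle_right = list(rows = 10:12, cols = 19:21),
         lower_right = list(rows = 19:21, cols = 19:21)))
}

#' Average signal enrichment of a 21 x 21 pileup matrix
#'
#' The mean of the 3 x 3 centre block (rows 10-12 x cols 10-12, 1-based,
#' loop at the centre) divided by the mean over the union of five 3 x 3
#' background blocks: upper left (1-3 x 1-3), upper middle (1-3 x
#' 10-12), upper right (1-3 x 19-21), middle right (10-12 x 19-21) and
#' lower right (19-21 x 19-21). Missing pixels are dropped from the
#' means. A zero background mean makes the enrichment infinite; such
#' matrices are reported as `Inf` and excluded from aggregates.
#'
#' @param matrix A 21 x 21 `cc_pileup` (or plain) matrix.
#' @return A scalar enrichment (`Inf` marks the excluded
#'   zero-background case).
#' @export
signal_enrichment <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != 21 || ncol(matrix) != 21) {
    abort("signal enrichment is defined for 21 x 21 pileup matrices")
  }
  b <- enrichment_blocks()
  num <- mean(matrix[b$center$rows, b$center$cols], na.rm = TRUE)
  bg <- unlist(lapply(b$background,
                      function(bl) matrix[bl$rows, bl$cols]))
  den <- mean(bg, na.rm = TRUE)
  if (is.nan(num) || is.nan(den)) return(NA_real_)
  if (den == 0) return(Inf)
  num / den
}

#' Aggregate signal enrichment over candidate loops
#'
#' Computes one pileup per loop and averages the finite enrichments
#' (infinite/zero-background cases are excluded, mirroring their
#' exclusion from published averages); also returns the element-wise
#' mean observed/expected matrix for plotting.
#'
#' @param loops Loop-bin tibble.
#' @param pairs Pairs tibble (or a [bin_counts()] table).
#' @param expected Optional `cc_expected`; computed from `pairs` when
#'   absent.
#' @param bin_size Bin side in bp (default 5000).
#' @param flank Window half-width in bins (default 10).
#' @return A list: `mean_enrichment` (over finite values), `n_finite`,
#'   `enrichments` (per-loop tibble), `mean_matrix` (`cc_pileup`).
#' @export
aggregate_enrichment <- function(loops, pairs, expected = NULL,
                                 bin_size = 5000, flank = 10) {
  if (nrow(loops) == 0) abort("no loops supplied")
  counts <- if (all(c("bin_x", "bin_y", "count") %in% names(pairs))) pairs
            else bin_counts(pairs, bin_size = bin_size)
  if (is.null(expected)) {
    expected <- expected_by_distance(counts, bin_size = bin_size,
                                     chrom_sizes = attr(pairs, "chromsizes"))
  }
  enr <- numeric(nrow(loops))
  acc <- NULL; n_acc <- 0
  for (i in seq_len(nrow(loops))) {
    m <- pileup_at(loops[i, ], counts, expected, flank = flank)
    if (is.null(m)) { enr[i] <- NA_real_; next }
    enr[i] <- signal_enrichment(m)
    mm <- unclass(m); mm[is.na(mm)] <- 0
    acc <- if (is.null(acc)) mm else acc + mm
    n_acc <- n_acc + 1
  }
  finite <- is.finite(enr)
  if (!any(finite)) abort("no loop has a finite signal enrichment")
  structure(
    list(mean_enrichment = mean(enr[finite]), n_finite = sum(finite),
         enrichments = mutate(loops, enrichment = enr),
         mean_matrix = structure(acc / max(n_acc, 1),
                                 class = c("cc_pileup", "matrix"))),
    class = "cc_enrichment")
}

#' @export
print.cc_enrichment <- function(x, ...) {
  cat(sprintf("<signal enrichment> mean %.3f over %d finite loop(s)\n",
              x$mean_enrichment, x$n_finite))
  invisible(x)
}

#' Write pileup matrices as TSV
#'
#' @param matrices A `cc_pileup` or list of them.
#' @param path Output path; matrices are stacked with a blank line
#'   between them.
#' @return `path`, invisibly.
#' @export
write_pileups <- function(matrices, path) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in matrices) {
    utils::write.table(unclass(m), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}
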