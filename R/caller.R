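#' Per-pair Voronoi density observations for background fitting
#'
#' For each intrachromosomal read pair, computes the genomic distance
#' `|pos2 - pos1|` and the natural log of its Voronoi density (the
#' reciprocal clipped-cell area, times the multiplicity of coincident
#' pairs) from the raw, unsmoothed diagram over the full chromosome
#' square. The diagram is built from all pairs of the chromosome
#' (upper-triangle points, no reflection — densities must come from
#' actual neighbours); pairs closer than `min_distance` are excluded
#' from the returned observations (self-ligation artefacts have
#' distance near 0), but still shape their neighbours' cells.
#'
#' @param pairs Pairs tibble (one chromosome's intrachromosomal records;
#'   [call_loops()] handles the per-chromosome split).
#' @param chrom_length Chromosome length in bp; defaults to the
#'   `chromsizes` attribute of `pairs`, else the maximum position seen.
#' @param min_distance Minimum pair distance in bp kept for fitting
#'   (default 1000).
#' @return A tibble `read_id`, `chrom`, `pos1`, `pos2`, `distance`,
#'   `log_distance`, `log_density` (natural logs).
#' @export
density_observations <- function(pairs, chrom_length = NULL,
                                 min_distance = 1000) {
  pairs <- pairs[pairs$chrom1 == pairs$chrom2, ]
  if (nrow(pairs) == 0) abort("no intrachromosomal pairs")
  chrom <- unique(pairs$chrom1)
  if (length(chrom) != 1) {
    abort("density_observations expects a single chromosome; see call_loops()")
  }
  if (is.null(chrom_length)) {
    cs <- attr(pairs, "chromsizes")
    chrom_length <- if (!is.null(cs) && chrom %in% cs$name) {
      cs$length[match(chrom, cs$name)]
    } else {
      max(pairs$pos1, pairs$pos2)
    }
  }
  pairs <- normalize_pairs(pairs, chrom_order = chrom)
  vp <- viewport(chrom, 0, chrom_length)
  x <- pairs$pos1 - 1
  y <- pairs$pos2 - 1
  d <- build_voronoi(tibble(x = x, y = y), vp)
  key <- paste(x, y, sep = "\r")
  cell <- match(key, paste(d$cells$x, d$cells$y, sep = "\r"))
  dens <- d$cells$density[cell]
  dist <- abs(pairs$pos2 - pairs$pos1)
  keep <- dist >= min_distance
  tibble(read_id = pairs$read_id[keep], chrom = chrom,
         pos1 = pairs$pos1[keep], pos2 = pairs$pos2[keep],
         distance = dist[keep], log_distance = log(dist[keep]),
         log_density = log(dens[keep]))
}

#' Robust log-log fit of background density against distance
#'
#' Fits `log_density ~ log_distance` with an MM-type robust regression
#' (bisquare psi, 95% Gaussian efficiency, via [MASS::rlm()]); the
#' prediction is the expected background contact density as a function
#' of genomic distance, and the robust residual scale feeds the
#' one-sided z-test in [score_pairs()].
#'
#' @param observations Tibble from [density_observations()].
#' @param min_obs Minimum number of observations (default 50).
#' @param estimator `"MM"` (default) or `"M"` (Huber M-estimation), for
#'   sensitivity analyses.
#' @return A `cc_background_fit`: `intercept`, `slope`, `scale` (robust
#'   residual scale), `n`, `estimator`.
#' @examples
#' obs <- tibble::tibble(log_distance = log(1000:1100),
#'                       log_density = 2 - log(1000:1100))
#' fit_background(obs)
#' @export
fit_background <- function(observations, min_obs = 50,
                           estimator = c("MM", "M")) {
  estimator <- match.arg(estimator)
  obs <- observations
  if (nrow(obs) < min_obs) {
    abort(sprintf("need >= %d observations to fit the background, got %d",
                  min_obs, nrow(obs)))
  }
  if (var(obs$log_distance) == 0) {
    abort("zero variance in log_distance: all pairs at one distance")
  }
  # (near-)noiseless inputs break the M-scale iteration; report the
  # exact least-squares line with its (vanishing) residual scale instead
  ls_fit <- stats::lm(log_density ~ log_distance, data = obs)
  if (stats::mad(stats::residuals(ls_fit)) <
      1e-10 * max(1, stats::sd(obs$log_density))) {
    cf <- coef(ls_fit)
    return(structure(
      list(intercept = unname(cf[1]), slope = unname(cf[2]),
           scale = stats::sd(stats::residuals(ls_fit)), n = nrow(obs),
           estimator = estimator, converged = TRUE),
      class = "cc_background_fit"))
  }
  fit <- if (estimator == "MM") {
    MASS::rlm(log_density ~ log_distance, data = obs, method = "MM",
              psi = MASS::psi.bisquare, maxit = 100)
  } else {
    MASS::rlm(log_density ~ log_distance, data = obs, method = "M",
              psi = MASS::psi.huber, maxit = 100)
  }
  cf <- coef(fit)
  structure(
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         scale = fit$s, n = nrow(obs), estimator = estimator,
         converged = fit$converged),
    class = "cc_background_fit"
  )
}

#' @export
print.cc_background_fit <- function(x, ...) {
  cat(sprintf(
    "<background fit> log_density = %.4f %+.4f * log_distance (%s, scale %.4f, n = %d)\n",
    x$intercept, x$slope, x$estimator, x$scale, x$n))
  invisible(x)
}

#' One-sided z-scores and p-values against the background fit
#'
#' `z = (log_density - predicted) / scale`; `p` is the upper-tail
#' standard normal probability (the alternative is a higher density than
#' the distance-decay background).
#'
#' @param observations Tibble from [density_observations()].
#' @param fit A `cc_background_fit`.
#' @return The observations with columns `z` and `p` appended.
#' @export
score_pairs <- function(observations, fit) {
  stopifnot(inherits(fit, "cc_background_fit"))
  expected <- fit$intercept + fit$slope * observations$log_distance
  z <- (observations$log_density - expected) / fit$scale
  mutate(observations, z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg selection at a target false discovery rate
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(n)`, find
#' the largest `k` with `p(k) <= fdr * k / n` and retain the `k`
#' smallest.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param fdr Target false discovery rate (default 0.10).
#' @return Integer indices of the retained hypotheses (empty when none).
#' @export
bh_select <- function(p_values, fdr = 0.10) {
  if (length(p_values) == 0) return(integer())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  which(p.adjust(p_values, method = "BH") <= fdr)
}

#' Call high-frequency contact bins from Voronoi densities
#'
#' The full identification pipeline, per chromosome: raw (unsmoothed)
#' Voronoi densities over the chromosome square, robust log-log
#' background fit, one-sided z-test per read pair, Benjamini-Hochberg
#' retention at `fdr`, then counting retained pairs in `bin_size` square
#' bins (grid anchored at coordinate 0, bin `k = [k*bin_size, (k+1)*
#' bin_size)`) and keeping bins supported by at least `min_support`
#' retained pairs.
#'
#' @param pairs Pairs tibble; interchromosomal records are ignored (the
#'   background model is distance-based).
#' @param fdr Pairwise false discovery rate (default 0.10).
#' @param bin_size Bin side in bp (default 5000).
#' @param min_support Minimum retained pairs per emitted bin (default 5).
#' @param min_distance Minimum pair distance for fitting/scoring
#'   (default 1000 bp).
#' @param min_obs Chromosomes with fewer observations are skipped with a
#'   warning (default 50).
#' @param chrom_sizes Optional tibble `name`,`length`; defaults to the
#'   `chromsizes` attribute of `pairs`.
#' @param pooled Fit one genome-wide background instead of one per
#'   chromosome (default `FALSE`: distance decay varies by chromosome).
#' @return A tibble `chrom`, `bin_x`, `bin_y`, `support`, `mean_z`
#'   (upper triangle, `bin_x <= bin_y`), with attribute `bin_size`.
#' @export
call_loops <- function(pairs, fdr = 0.10, bin_size = 5000, min_support = 5,
                       min_distance = 1000, min_obs = 50,
                       chrom_sizes = attr(pairs, "chromsizes"),
                       pooled = FALSE) {
  empty <- tibble(chrom = character(), bin_x = numeric(), bin_y = numeric(),
                  support = integer(), mean_z = numeric())
  attr(empty, "bin_size") <- bin_size
  intra <- pairs[pairs$chrom1 == pairs$chrom2, ]
  if (nrow(intra) == 0) {
    warn("no intrachromosomal pairs; nothing to call")
    return(empty)
  }
  chroms <- unique(intra$chrom1)
  obs_list <- list()
  for (ch in chroms) {
    sub <- intra[intra$chrom1 == ch, ]
    attr(sub, "chromsizes") <- chrom_sizes
    if (nrow(sub) < min_obs) {
      warn(sprintf("chromosome %s skipped: fewer than %d usable observations",
                   ch, min_obs))
      next
    }
    obs <- density_observations(sub, min_distance = min_distance)
    if (nrow(obs) < min_obs) {
      warn(sprintf("chromosome %s skipped: fewer than %d usable observations",
                   ch, min_obs))
      next
    }
    obs_list[[ch]] <- obs
  }
  if (length(obs_list) == 0) return(empty)

  score_one <- function(obs, fit) {
    scored <- score_pairs(obs, fit)
    scored[bh_select(scored$p, fdr = fdr), ]
  }
  retained <- if (pooled) {
    all_obs <- bind_rows(obs_list)
    score_one(all_obs, fit_background(all_obs, min_obs = min_obs))
  } else {
    bind_rows(lapply(obs_list, function(obs) {
      score_one(obs, fit_background(obs, min_obs = min_obs))
    }))
  }
  if (nrow(retained) == 0) return(empty)
  out <- retained |>
    mutate(bin_x = floor((.data$pos1 - 1) / bin_size),
           bin_y = floor((.data$pos2 - 1) / bin_size)) |>
    group_by(.data$chrom, .data$bin_x, .data$bin_y) |>
    summarise(support = dplyr::n(), mean_z = mean(.data$z),
              .groups = "drop") |>
    filter(.data$support >= min_support) |>
    arrange(.data$chrom, .data$bin_x, .data$bin_y)
  attr(out, "bin_size") <- bin_size
  out
}

#' Partition two loop-bin lists by exact bin identity
#'
#' Bins match when chromosome, `bin_x` and `bin_y` all agree; the two
#' inputs must use the same bin size.
#'
#' @param called,reference Loop-bin tibbles (`chrom`, `bin_x`, `bin_y`,
#'   ...), e.g. from [call_loops()].
#' @return A list `common`, `called_only`, `reference_only` of tibbles,
#'   plus `counts`, a named integer vector of the three class sizes.
#' @export
overlap_bins <- function(called, reference) {
  bs1 <- attr(called, "bin_size"); bs2 <- attr(reference, "bin_size")
  if (!is.null(bs1) && !is.null(bs2) && bs1 != bs2) {
    abort(sprintf("bin sizes differ: %s vs %s", bs1, bs2))
  }
  key <- function(d) paste(d$chrom, d$bin_x, d$bin_y, sep = "\r")
  kc <- key(called); kr <- key(reference)
  common <- called[kc %in% kr, ]
  called_only <- called[!(kc %in% kr), ]
  reference_only <- reference[!(kr %in% kc), ]
  list(common = common, called_only = called_only,
       reference_only = reference_only,
       counts = c(common = nrow(common), called_only = nrow(called_only),
                  reference_only = nrow(reference_only)))
}

#' Write called loop bins to disk
#'
#' @param loops Loop-bin tibble from [call_loops()].
#' @param path Output path.
#' @param format `"tsv"` (chrom, bin_x_start, bin_y_start, support,
#'   mean_z) or `"interact"` (score = support).
#' @param bin_size Bin size in bp (defaults to the tibble's attribute).
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path, format = c("tsv", "interact"),
                        bin_size = attr(loops, "bin_size")) {
  format <- match.arg(format)
  if (is.null(bin_size)) abort("bin_size unknown; pass it explicitly")
  if (format == "tsv") {
    out <- tibble(chrom = loops$chrom,
                  bin_x_start = loops$bin_x * bin_size,
                  bin_y_start = loops$bin_y * bin_size,
                  support = loops$support, mean_z = loops$mean_z)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    rec <- tibble(source_chrom = loops$chrom,
                  source_start = loops$bin_x * bin_size,
                  source_end = (loops$bin_x + 1) * bin_size,
                  target_chrom = loops$chrom,
                  target_start = loops$bin_y * bin_size,
                  target_end = (loops$bin_y + 1) * bin_size,
                  score = loops$support,
                  name = sprintf("bin_%s_%d_%d", loops$chrom, loops$bin_x,
                                 loops$bin_y))
    write_interact(rec, path)
  }
  invisible(path)
}

#' Read loop bins written by [write_loops()]
#'
#' @param path TSV path.
#' @param bin_size Bin size in bp used when writing.
#' @return A loop-bin tibble with attribute `bin_size`.
#' @export
read_loops <- function(path, bin_size = 5000) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", rep("numeric", 4)))
  out <- tibble(chrom = d$chrom, bin_x = d$bin_x_start / bin_size,
                bin_y = d$bin_y_start / bin_size,
                support = as.integer(d$support), mean_z = d$mean_z)
  attr(out, "bin_size") <- bin_size
  out
}
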