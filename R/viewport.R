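#' Define a rectangular query region on a pair of chromosomal axes
#'
#' A viewport is the rectangle spanned by an interval on the x axis
#' (`chrom_x:start_x-end_x`) and an interval on the y axis. All viewport
#' coordinates are 0-based half-open base-pair intervals; pairs-format
#' positions (1-based) are converted once, at the parsing boundary, by
#' `pos - 1`.
#'
#' @param chrom_x,chrom_y Chromosome names for the two axes.
#' @param start_x,end_x,start_y,end_y Interval bounds in bp, 0-based
#'   half-open, `end > start`.
#' @return An object of class `cc_viewport`.
#' @examples
#' viewport("chr3", 3e6, 4.5e6)
#' @export
viewport <- function(chrom_x, start_x, end_x,
                     chrom_y = chrom_x, start_y = start_x, end_y = end_x) {
  stopifnot(is.character(chrom_x), is.character(chrom_y))
  start_x <- as.numeric(start_x); end_x <- as.numeric(end_x)
  start_y <- as.numeric(start_y); end_y <- as.numeric(end_y)
  if (!(end_x > start_x && end_y > start_y)) {
    abort("viewport intervals must satisfy end > start on both axes")
  }
  if ((end_x - start_x) * (end_y - start_y) > 2^53) {
    abort("viewport area exceeds 2^53 bp^2; coordinates are not exactly representable")
  }
  structure(
    list(chrom_x = chrom_x, start_x = start_x, end_x = end_x,
         chrom_y = chrom_y, start_y = start_y, end_y = end_y),
    class = "cc_viewport"
  )
}

#' @export
print.cc_viewport <- function(x, ...) {
  cat(sprintf("<viewport> %s:%s-%s x %s:%s-%s (0-based half-open)\n",
              x$chrom_x, format(x$start_x, big.mark = ","),
              format(x$end_x, big.mark = ","),
              x$chrom_y, format(x$start_y, big.mark = ","),
              format(x$end_y, big.mark = ",")))
  invisible(x)
}

viewport_area <- function(vp) {
  (vp$end_x - vp$start_x) * (vp$end_y - vp$start_y)
}

viewport_on_diagonal <- function(vp) {
  vp$chrom_x == vp$chrom_y && vp$start_x == vp$start_y && vp$end_x == vp$end_y
}

#' Parse a genomic region string
#'
#' Accepts the conventional 1-based closed form `"chr1:1-500"` and returns
#' the 0-based half-open interval used internally (here `[0, 500)`).
#'
#' @param x A string `"chrom:start-end"` (1-based, closed) or an existing
#'   region list.
#' @return A list with elements `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(x) {
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) return(x)
  stopifnot(is.character(x), length(x) == 1)
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) abort(sprintf("cannot parse region '%s' (expected chrom:start-end)", x))
  start1 <- as.numeric(gsub(",", "", m[3]))
  end1 <- as.numeric(gsub(",", "", m[4]))
  if (!(start1 >= 1 && end1 >= start1)) abort("region must satisfy 1 <= start <= end")
  list(chrom = m[2], start = start1 - 1, end = end1)
}
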