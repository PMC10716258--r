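#' Read 3C read pairs from a 4DN pairs-format file
#'
#' Parses the 4DN pairs format: a header of `#`-prefixed lines that must
#' contain a `## pairs format` version line, followed by tab-separated
#' records with at least the seven standard columns
#' `readID chr1 pos1 chr2 pos2 strand1 strand2`. Plain-text and
#' gzip/BGZF-compressed files are handled transparently (BGZF is a
#' gzip-conformant framing). Extra columns beyond the seventh are kept
#' verbatim in an `extra` column.
#'
#' Positions in the file are 1-based, per the pairs standard, and are
#' returned unchanged in `pos1`/`pos2`. When `region_a`/`region_b` are
#' supplied the records are upper-triangle normalized (side 1 not after
#' side 2 under (chromosome order, position)) and exactly those whose
#' normalized sides fall in `region_a` x `region_b` are returned.
#' Querying a chromosome absent from the file yields an empty result with
#' a warning, not an error.
#'
#' @param path Path to a `.pairs` or `.pairs.gz` file.
#' @param region_a,region_b Optional regions (string `"chr:start-end"`,
#'   1-based closed, or a list from [parse_region()]) for the two sides.
#' @param index Optional [build_pairs_index()] result (or path to its JSON
#'   sidecar); when given, only the byte ranges whose tiles overlap the
#'   query are read.
#' @return A tibble with columns `read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2`, `extra`, carrying the header lines and
#'   the chromosome-size table as attributes `header` and `chromsizes`.
#' @examples
#' f <- tempfile(fileext = ".pairs")
#' writeLines(c("## pairs format v1.0", "#chromsize: chr1 1000",
#'              "r1\tchr1\t100\tchr1\t900\t+\t-"), f)
#' read_pairs(f)
#' @export
read_pairs <- function(path, region_a = NULL, region_b = NULL, index = NULL) {
  if (!file.exists(path)) abort(sprintf("pairs file not found: %s", path))
  if (!is.null(index) && !is.null(region_a) && !is.null(region_b)) {
    return(read_pairs_indexed(path, index, region_a, region_b))
  }
  lines <- read_text_lines(path)
  parsed <- parse_pairs_lines(lines)
  out <- parsed$records
  if (!is.null(region_a) || !is.null(region_b)) {
    if (is.null(region_a) || is.null(region_b)) {
      abort("supply both region_a and region_b, or neither")
    }
    out <- filter_pairs_region(out, parse_region(region_a),
                               parse_region(region_b), parsed$chrom_order)
  }
  attr(out, "header") <- parsed$header
  attr(out, "chromsizes") <- parsed$chromsizes
  out
}

is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# reads a whole (possibly gzip/BGZF) text file as lines
read_text_lines <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  readLines(con)
}

parse_pairs_lines <- function(lines, first_line = 1L) {
  is_header <- startsWith(lines, "#")
  n_head <- match(FALSE, is_header, nomatch = length(lines) + 1L) - 1L
  header <- lines[seq_len(n_head)]
  if (first_line == 1L && !any(grepl("^## pairs format", header))) {
    abort("not a pairs file: missing '## pairs format' header line")
  }
  body <- lines[seq_len(length(lines) - n_head) + n_head]
  body <- body[!startsWith(body, "#")]
  chromsizes <- parse_chromsizes(header)
  records <- parse_pairs_body(body, first_line + n_head)
  chrom_order <- chromsizes$name
  if (length(chrom_order) == 0) {
    chrom_order <- unique(c(records$chrom1, records$chrom2))
  }
  list(header = header, chromsizes = chromsizes, records = records,
       chrom_order = chrom_order)
}

parse_chromsizes <- function(header) {
  cs <- header[startsWith(header, "#chromsize:")]
  if (length(cs) == 0) {
    return(tibble(name = character(), length = numeric()))
  }
  parts <- strsplit(trimws(sub("^#chromsize:", "", cs)), "[ \t]+")
  tibble(name = vapply(parts, `[[`, "", 1),
         length = as.numeric(vapply(parts, `[[`, "", 2)))
}

parse_pairs_body <- function(body, line_offset = 1L) {
  empty <- tibble(read_id = character(), chrom1 = character(),
                  pos1 = numeric(), chrom2 = character(), pos2 = numeric(),
                  strand1 = character(), strand2 = character(),
                  extra = character())
  if (length(body) == 0) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7)) {
    bad <- which(nf < 7)[1]
    abort(sprintf("line %d: expected >= 7 tab-separated columns, got %d",
                  bad + line_offset - 1L, nf[bad]))
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  pos1 <- suppressWarnings(as.numeric(get(3)))
  pos2 <- suppressWarnings(as.numeric(get(5)))
  bad <- which(is.na(pos1) | is.na(pos2) | pos1 != floor(pos1) |
                 pos2 != floor(pos2) | pos1 < 1 | pos2 < 1)
  if (length(bad) > 0) {
    abort(sprintf("line %d: positions must be integers >= 1",
                  bad[1] + line_offset - 1L))
  }
  extra <- vapply(fields, function(f) {
    if (length(f) > 7) paste(f[-(1:7)], collapse = "\t") else NA_character_
  }, "")
  tibble(read_id = get(1), chrom1 = get(2), pos1 = pos1,
         chrom2 = get(4), pos2 = pos2, strand1 = get(6), strand2 = get(7),
         extra = extra)
}

#' Upper-triangle normalize read pairs
#'
#' Swaps the two sides of any record for which side 2 precedes side 1
#' under the lexicographic order (chromosome rank, position), so that all
#' intrachromosomal records satisfy `pos1 <= pos2`. Chromosome rank is the
#' order of appearance in the file header (or, failing that, in the data).
#'
#' @param pairs A pairs tibble from [read_pairs()].
#' @param chrom_order Character vector giving the chromosome order.
#' @return The pairs tibble with sides swapped where needed.
#' @export
normalize_pairs <- function(pairs, chrom_order = NULL) {
  if (nrow(pairs) == 0) return(pairs)
  if (is.null(chrom_order)) {
    cs <- attr(pairs, "chromsizes")
    chrom_order <- if (!is.null(cs) && nrow(cs) > 0) cs$name else
      unique(c(pairs$chrom1, pairs$chrom2))
  }
  r1 <- match(pairs$chrom1, chrom_order)
  r2 <- match(pairs$chrom2, chrom_order)
  swap <- (r2 < r1) | (r1 == r2 & pairs$pos2 < pairs$pos1)
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- pairs[swap, ]
    pairs[swap, c("chrom1", "pos1", "strand1")] <-
      tmp[, c("chrom2", "pos2", "strand2")]
    pairs[swap, c("chrom2", "pos2", "strand2")] <-
      tmp[, c("chrom1", "pos1", "strand1")]
  }
  pairs
}

filter_pairs_region <- function(records, ra, rb, chrom_order) {
  known <- unique(c(records$chrom1, records$chrom2, chrom_order))
  for (ch in setdiff(unique(c(ra$chrom, rb$chrom)), known)) {
    warn(sprintf("chromosome '%s' not present in pairs file", ch))
  }
  records <- normalize_pairs(records, chrom_order)
  keep <- records$chrom1 == ra$chrom &
    records$pos1 - 1 >= ra$start & records$pos1 - 1 < ra$end &
    records$chrom2 == rb$chrom &
    records$pos2 - 1 >= rb$start & records$pos2 - 1 < rb$end
  records[keep, ]
}

#' Write read pairs in the 4DN pairs format
#'
#' @param pairs Pairs tibble (columns as returned by [read_pairs()]).
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param chromsizes Optional tibble `name`,`length` emitted as
#'   `#chromsize:` header lines (defaults to the `chromsizes` attribute).
#' @param extra_header Additional header lines (without trailing newline).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, chromsizes = attr(pairs, "chromsizes"),
                        extra_header = NULL) {
  header <- c("## pairs format v1.0",
              "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2")
  if (!is.null(chromsizes) && nrow(chromsizes) > 0) {
    header <- c(header, sprintf("#chromsize: %s %s", chromsizes$name,
                                fmt_num(chromsizes$length)))
  }
  header <- c(header, extra_header)
  body <- serialize_pairs_body(pairs)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(c(header, body), con)
  close(con)
  invisible(path)
}

serialize_pairs_body <- function(pairs) {
  if (nrow(pairs) == 0) return(character())
  base <- paste(pairs$read_id, pairs$chrom1, fmt_num(pairs$pos1),
                pairs$chrom2, fmt_num(pairs$pos2), pairs$strand1,
                pairs$strand2, sep = "\t")
  has_extra <- !is.na(pairs$extra)
  base[has_extra] <- paste(base[has_extra], pairs$extra[has_extra], sep = "\t")
  base
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

# ---- tile index ------------------------------------------------------------

#' Build a coarse tile index over a sorted pairs file
#'
#' Scans the file once and records, for every (chrom1, chrom2, tile) key —
#' where the tile is `floor((pos1 - 1) / tile_size)` — the byte ranges of
#' the lines carrying that key. Offsets refer to the uncompressed stream,
#' so the same index serves plain and gzip/BGZF files (`seek()` on a gzip
#' connection addresses uncompressed positions). Region queries through
#' the index read only the matching byte ranges.
#'
#' @param path Pairs file sorted by (chrom1, pos1).
#' @param tile_size Tile width in bp (default 1 Mb).
#' @param sorted Set `FALSE` to accept unsorted input; the index then
#'   carries no blocks and queries fall back to full scans.
#' @return A `cc_pairs_index` object.
#' @export
build_pairs_index <- function(path, tile_size = 1e6, sorted = TRUE) {
  stopifnot(tile_size > 0)
  lines <- read_text_lines(path)
  is_header <- startsWith(lines, "#")
  n_head <- match(FALSE, is_header, nomatch = length(lines) + 1L) - 1L
  parsed <- parse_pairs_lines(lines)
  rec <- parsed$records
  # uncompressed byte offset of each line (assumes "\n" line endings)
  nbytes <- nchar(lines, type = "bytes") + 1L
  offsets <- cumsum(c(0, nbytes))
  body_idx <- which(!startsWith(lines, "#"))
  blocks <- tibble(chrom1 = character(), chrom2 = character(),
                   tile = numeric(), offset = numeric(), end = numeric())
  if (nrow(rec) > 0 && sorted) {
    rank1 <- match(rec$chrom1, parsed$chrom_order)
    ooo <- which(diff(rank1) < 0 | (diff(rank1) == 0 & diff(rec$pos1) < 0))
    if (length(ooo) > 0) {
      abort(sprintf(
        "pairs file not sorted by (chrom1, pos1): line %d is out of order (use sorted = FALSE to index anyway)",
        body_idx[ooo[1] + 1L]))
    }
  }
  if (nrow(rec) > 0 && sorted) {
    key <- paste(rec$chrom1, rec$chrom2, floor((rec$pos1 - 1) / tile_size),
                 sep = "\r")
    runs <- rle(key)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    parts <- strsplit(runs$values, "\r", fixed = TRUE)
    blocks <- tibble(
      chrom1 = vapply(parts, `[[`, "", 1),
      chrom2 = vapply(parts, `[[`, "", 2),
      tile = as.numeric(vapply(parts, `[[`, "", 3)),
      offset = offsets[body_idx[starts]],
      end = offsets[body_idx[stops] + 1L]
    )
  }
  structure(
    list(version = 1L, tile_size = tile_size,
         sorted = sorted,
         chromosomes = parsed$chromsizes,
         chrom_order = parsed$chrom_order,
         blocks = blocks),
    class = "cc_pairs_index"
  )
}

#' @export
print.cc_pairs_index <- function(x, ...) {
  cat(sprintf("<pairs index> tile %s bp, %d chromosome(s), %d block(s)\n",
              fmt_num(x$tile_size), length(x$chrom_order), nrow(x$blocks)))
  invisible(x)
}

#' Write / read the JSON sidecar form of a pairs index
#'
#' The sidecar is a versioned JSON document with fields `version`,
#' `tile_size`, `sorted`, `chromosomes` (name/length), `chrom_order` and
#' `blocks` (chrom1, chrom2, tile, offset, end — uncompressed byte ranges).
#'
#' @param index A `cc_pairs_index`.
#' @param path Sidecar path (conventionally `<pairs>.vcx.json`).
#' @return `path` (write) or the index (read).
#' @export
write_pairs_index <- function(index, path) {
  stopifnot(inherits(index, "cc_pairs_index"))
  jsonlite::write_json(unclass(index), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pairs_index
#' @export
read_pairs_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$chromosomes <- as_tibble(x$chromosomes)
  x$blocks <- as_tibble(x$blocks)
  if (nrow(x$blocks) == 0) {
    x$blocks <- tibble(chrom1 = character(), chrom2 = character(),
                       tile = numeric(), offset = numeric(), end = numeric())
  }
  structure(x, class = "cc_pairs_index")
}

read_pairs_indexed <- function(path, index, region_a, region_b) {
  if (is.character(index)) index <- read_pairs_index(index)
  stopifnot(inherits(index, "cc_pairs_index"))
  ra <- parse_region(region_a)
  rb <- parse_region(region_b)
  if (!index$sorted || nrow(index$blocks) == 0) {
    return(read_pairs(path, region_a, region_b))
  }
  for (ch in setdiff(unique(c(ra$chrom, rb$chrom)), index$chrom_order)) {
    warn(sprintf("chromosome '%s' not present in pairs file", ch))
  }
  ts <- index$tile_size
  pick <- function(rfrom, rto) {
    with(index$blocks,
         chrom1 == rfrom$chrom & chrom2 == rto$chrom &
           tile >= floor(rfrom$start / ts) & tile <= floor((rfrom$end - 1) / ts))
  }
  sel <- index$blocks[pick(ra, rb) | pick(rb, ra), ]
  if (nrow(sel) == 0) {
    rec <- parse_pairs_body(character())
  } else {
    rng <- sel[order(sel$offset), c("offset", "end")]
    # merge touching/overlapping byte ranges
    merged <- list(); cur <- c(rng$offset[1], rng$end[1])
    for (i in seq_len(nrow(rng))[-1]) {
      if (rng$offset[i] <= cur[2]) cur[2] <- max(cur[2], rng$end[i])
      else { merged[[length(merged) + 1]] <- cur; cur <- c(rng$offset[i], rng$end[i]) }
    }
    merged[[length(merged) + 1]] <- cur
    chunks <- character()
    if (is_gzip(path)) {
      # gzip/BGZF: the stream cannot be seeked across member boundaries,
      # so decompress sequentially and slice lines by their uncompressed
      # offsets (only the selected lines are parsed)
      lines <- read_text_lines(path)
      off <- cumsum(c(0, nchar(lines, type = "bytes") + 1L))
      for (m in merged) {
        sel <- off[-length(off)] >= m[1] & off[-length(off)] < m[2]
        chunks <- c(chunks, lines[sel])
      }
    } else {
      con <- file(path, "rb")
      on.exit(close(con))
      for (m in merged) {
        seek(con, m[1])
        raw <- readBin(con, "raw", n = m[2] - m[1])
        chunks <- c(chunks, strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1]])
      }
    }
    rec <- parse_pairs_body(chunks[!startsWith(chunks, "#") & nzchar(chunks)])
  }
  out <- filter_pairs_region(rec, ra, rb, index$chrom_order)
  attr(out, "chromsizes") <- index$chromosomes
  out
}

# ---- interact format -------------------------------------------------------

#' Read and write interact-format contact lists
#'
#' The interact browser track format stores one pairwise interaction per
#' line with two genomic intervals (source and target), a score and a
#' name; coordinates are 0-based half-open on disk. The full 18-column
#' layout and a compact 8-column layout (`sourceChrom sourceStart
#' sourceEnd targetChrom targetStart targetEnd score name`) are both
#' accepted; `write_interact()` emits the full layout by default.
#'
#' @param path File path. `browser`/`track` preamble lines are skipped.
#' @return A tibble with columns `source_chrom`, `source_start`,
#'   `source_end`, `target_chrom`, `target_start`, `target_end`, `score`,
#'   `name`.
#' @export
read_interact <- function(path) {
  empty <- tibble(source_chrom = character(), source_start = numeric(),
                  source_end = numeric(), target_chrom = character(),
                  target_start = numeric(), target_end = numeric(),
                  score = numeric(), name = character())
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|browser|track)", lines)]
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 18)) {
    g <- function(i) vapply(fields, `[[`, "", i)
    out <- tibble(source_chrom = g(9), source_start = as.numeric(g(10)),
                  source_end = as.numeric(g(11)),
                  target_chrom = g(14), target_start = as.numeric(g(15)),
                  target_end = as.numeric(g(16)),
                  score = as.numeric(g(5)), name = g(4))
  } else if (all(nf == 8)) {
    g <- function(i) vapply(fields, `[[`, "", i)
    out <- tibble(source_chrom = g(1), source_start = as.numeric(g(2)),
                  source_end = as.numeric(g(3)),
                  target_chrom = g(4), target_start = as.numeric(g(5)),
                  target_end = as.numeric(g(6)),
                  score = as.numeric(g(7)), name = g(8))
  } else {
    abort("interact file must have 18 (standard) or 8 (compact) columns")
  }
  bad <- which(out$source_start >= out$source_end |
                 out$target_start >= out$target_end)
  if (length(bad) > 0) {
    abort(sprintf("interact record %d: interval start must be < end", bad[1]))
  }
  if (any(out$score < 0)) abort("interact scores must be non-negative")
  out
}

#' @param records Interact tibble as returned by [read_interact()].
#' @param compact Write the 8-column compact layout instead of the
#'   18-column standard one.
#' @rdname read_interact
#' @export
write_interact <- function(records, path, compact = FALSE) {
  if (any(records$source_start >= records$source_end) ||
      any(records$target_start >= records$target_end)) {
    abort("interact record: interval start must be < end")
  }
  if (nrow(records) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  r <- records
  if (compact) {
    lines <- paste(r$source_chrom, fmt_num(r$source_start),
                   fmt_num(r$source_end), r$target_chrom,
                   fmt_num(r$target_start), fmt_num(r$target_end),
                   fmt_num(r$score), r$name, sep = "\t")
  } else {
    span_start <- pmin(r$source_start, r$target_start)
    span_end <- pmax(r$source_end, r$target_end)
    lines <- paste(r$source_chrom, fmt_num(span_start), fmt_num(span_end),
                   r$name, fmt_num(r$score), fmt_num(r$score), ".", "0",
                   r$source_chrom, fmt_num(r$source_start),
                   fmt_num(r$source_end), ".", ".",
                   r$target_chrom, fmt_num(r$target_start),
                   fmt_num(r$target_end), ".", ".", sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
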