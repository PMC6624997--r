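#' @title Bedgraph and BED input/output
#' @description Readers and writers for the plain-text interval formats the
#'   pipeline consumes and produces. All coordinates are 0-based, half-open
#'   (UCSC convention); adjacency means `end[i] == start[i+1]`.
#' @name genomic_io
NULL

empty_bedgraph <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             signal = numeric())
}

# Shortest decimal representation that round-trips to the same double.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- suppressWarnings(as.numeric(out)) != x
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out
}

is_data_line <- function(lines) {
  !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
}

parse_coord <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.na(v) & (v != floor(v) | v < 0)] <- NA_real_
  v
}

#' Read a UCSC bedgraph file
#'
#' Parses a 4-column bedgraph (chrom, start, end, signal). `track`, `browser`,
#' comment (`#`) and blank lines are skipped; space and tab delimiters are
#' both accepted. Rows with signal exactly 0 are dropped: a bedgraph for this
#' pipeline "omits regions containing 0 signal", so an explicit zero row is
#' semantically identical to a gap and must behave like one (it splits signal
#' blocks).
#'
#' @param path path to a bedgraph file.
#' @param strict if `TRUE` (default), any malformed row (fewer than 4 columns,
#'   non-integer or negative coordinates, `end <= start`, negative or
#'   non-numeric signal) or overlap between rows on one chromosome raises an
#'   error naming the offending line; if `FALSE`, offending rows are skipped
#'   with one summary warning.
#' @return a `data.table` with columns `chrom`, `start`, `end`, `signal`,
#'   sorted by (chrom, start), zero-signal rows removed.
#' @export
read_bedgraph <- function(path, strict = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("bedgraph file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- is_data_line(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) return(empty_bedgraph())

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  get_col <- function(i) {
    out <- rep(NA_character_, length(fields))
    ok <- nf >= i
    out[ok] <- vapply(fields[ok], `[[`, character(1L), i)
    out
  }
  chrom <- get_col(1L)
  start <- parse_coord(get_col(2L))
  end <- parse_coord(get_col(3L))
  signal <- suppressWarnings(as.numeric(get_col(4L)))

  bad <- nf < 4L | is.na(start) | is.na(end) | is.na(signal) |
    end <= start | signal < 0
  if (any(bad)) {
    if (strict)
      stop("malformed bedgraph row at line ", lineno[which(bad)[1L]],
           " of ", path)
    warning(sum(bad), " malformed bedgraph row(s) skipped in ", path)
  }
  ok <- !bad
  dt <- data.table(chrom = chrom[ok], start = as.integer(start[ok]),
                   end = as.integer(end[ok]), signal = signal[ok],
                   lineno = lineno[ok])
  dt <- dt[signal > 0]
  setorder(dt, chrom, start, end)

  # overlap check within chromosome (after sorting)
  if (nrow(dt) > 1L) {
    prev_end <- dt[, shift(cummax(end), fill = -1L), by = chrom]$V1
    ov <- dt$start < prev_end & prev_end >= 0L
    if (any(ov)) {
      if (strict)
        stop("overlapping bedgraph intervals at line ",
             dt$lineno[which(ov)[1L]], " of ", path)
      warning(sum(ov), " overlapping bedgraph row(s) skipped in ", path)
      dt <- dt[!ov]
    }
  }
  dt[, lineno := NULL]
  dt[]
}

#' Write intervals as a 4-column bedgraph
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  x <- as.data.table(x)
  if (nrow(x) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(paste(x$chrom, x$start, x$end, fmt_num(x$signal), sep = "\t"),
             path)
  invisible(path)
}

#' Read a BED file
#'
#' Reads BED3+ files such as reference peak sets. Column 4 is kept as `name`
#' when present. A numeric score is taken from `score_col` when given
#' (e.g. column 7 holding `-log10(FDR)` in narrowPeak-style files), otherwise
#' from column 5 when present. Score-based filtering of reference sets is the
#' caller's responsibility.
#'
#' @param path path to a BED file.
#' @param score_col 1-based index of the column holding a numeric score, or
#'   `NULL` for the default (column 5 when present).
#' @param strict as in [read_bedgraph()].
#' @return a `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, sorted by (chrom, start, end).
#' @export
read_bed <- function(path, score_col = NULL, strict = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("BED file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- is_data_line(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric()))

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  get_col <- function(i) {
    out <- rep(NA_character_, length(fields))
    ok <- nf >= i
    out[ok] <- vapply(fields[ok], `[[`, character(1L), i)
    out
  }
  chrom <- get_col(1L)
  start <- parse_coord(get_col(2L))
  end <- parse_coord(get_col(3L))
  bad <- nf < 3L | is.na(start) | is.na(end) | end <= start
  if (any(bad)) {
    if (strict)
      stop("malformed BED row at line ", lineno[which(bad)[1L]], " of ", path)
    warning(sum(bad), " malformed BED row(s) skipped in ", path)
  }
  sc_col <- if (!is.null(score_col)) as.integer(score_col)
            else if (any(nf >= 5L)) 5L else NA_integer_
  score <- if (is.na(sc_col)) rep(NA_real_, length(fields))
           else suppressWarnings(as.numeric(get_col(sc_col)))
  dt <- data.table(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), name = get_col(4L), score = score)
  dt <- dt[!bad]
  setorder(dt, chrom, start, end)
  dt[]
}

#' Write called peaks as a 6-column BED-like file
#'
#' One row per retained signal block, tab-delimited, no header:
#' chrom, start, end, total signal, max signal, and the max-signal component
#' span as `"chrom:start-end"`. Numeric columns use the shortest decimal
#' representation that round-trips. This 6-column dialect matches the output
#' convention of the widely used public release of this peak-calling approach
#' so that downstream tooling is compatible.
#'
#' @param path output path.
#' @param peaks a block set from [aggregate_blocks()] or [call_peaks()], or
#'   a data.frame with columns `chrom`, `start`,
#'   `end`, `total_signal`, `max_signal`, `max_start`, `max_end`.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(path, peaks) {
  b <- if (inherits(peaks, "block_set")) peaks$blocks else as.data.table(peaks)
  if (nrow(b) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  b <- as.data.table(b)
  setorder(b, chrom, start, end)
  prev_end <- b[, shift(cummax(end), fill = -1L), by = chrom]$V1
  if (any(b$start < prev_end & prev_end >= 0L))
    stop("internal error: retained peaks overlap on one chromosome; ",
         "blocks must be merged before writing")
  writeLines(paste(b$chrom, b$start, b$end,
                   fmt_num(b$total_signal), fmt_num(b$max_signal),
                   sprintf("%s:%d-%d", b$chrom, b$max_start, b$max_end),
                   sep = "\t"),
             path)
  invisible(path)
}
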