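#' Aggregate adjacent bedgraph intervals into signal blocks
#'
#' The core data reduction: maximal runs of adjacent (`end[i] == start[i+1]`)
#' nonzero intervals on one chromosome are concatenated into "signal blocks".
#' Each block carries its total signal
#' \deqn{t = \sum_i (\mathrm{end}_i - \mathrm{start}_i) \times \mathrm{signal}_i}
#' summed left-to-right in genomic order (so totals are bit-reproducible),
#' its maximum component signal, and the span of the component attaining that
#' maximum (leftmost on ties). Blocks are never merged across chromosomes.
#'
#' @param intervals a data.frame of nonzero coverage intervals with columns
#'   `chrom`, `start`, `end`, `signal`, sorted by (chrom, start),
#'   non-overlapping, all signals > 0 (as produced by [read_bedgraph()]).
#' @param merge_gap maximum zero-coverage gap (bp) bridged when concatenating
#'   intervals. The default 0 requires strict adjacency.
#' @param label dataset label (`"target"` or `"control"`), carried on the
#'   returned set.
#' @return a `block_set`: list with `blocks` (a `data.table` with columns
#'   `chrom`, `start`, `end`, `total_signal`, `max_signal`, `max_start`,
#'   `max_end`, `n_components`), `m` (block count) and `label`.
#' @examples
#' iv <- data.frame(chrom = "chr1", start = c(0L, 10L, 25L),
#'                  end = c(10L, 20L, 30L), signal = c(2, 3, 1))
#' aggregate_blocks(iv)$blocks
#' @export
aggregate_blocks <- function(intervals, merge_gap = 0, label = "target") {
  x <- as.data.table(intervals)
  need <- c("chrom", "start", "end", "signal")
  if (!all(need %in% names(x)))
    stop("intervals must have columns chrom, start, end, signal")
  if (nrow(x) == 0L)
    return(new_block_set(empty_blocks(), label))
  if (any(x$signal <= 0))
    stop("contract violation: aggregate_blocks() requires all signals > 0")
  if (is.unsorted_intervals(x))
    stop("contract violation: intervals must be sorted by (chrom, start) ",
         "and non-overlapping")
  newblk <- x$chrom != shift(x$chrom, fill = "") |
    x$start > shift(as.numeric(x$end), fill = -Inf) + merge_gap
  grp <- cumsum(newblk)
  blocks <- x[, .(
    chrom = chrom[1L],
    start = start[1L],
    end = end[.N],
    total_signal = sum((end - start) * signal),
    max_signal = max(signal),
    max_start = start[which.max(signal)],
    max_end = end[which.max(signal)],
    n_components = .N
  ), by = .(blk = grp)][, blk := NULL]
  new_block_set(blocks[], label)
}

is.unsorted_intervals <- function(x) {
  if (nrow(x) < 2L) return(FALSE)
  prev_chrom <- shift(x$chrom, fill = "")
  same <- x$chrom == prev_chrom
  prev_end <- shift(x$end, fill = -1L)
  prev_start <- shift(x$start, fill = -1L)
  any(same & (x$start < prev_start | x$start < prev_end)) ||
    is.unsorted(match(x$chrom, unique(x$chrom)))
}

empty_blocks <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             total_signal = numeric(), max_signal = numeric(),
             max_start = integer(), max_end = integer(),
             n_components = integer())
}

new_block_set <- function(blocks, label = "target") {
  structure(list(blocks = blocks, m = nrow(blocks), label = label),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %s: %d signal block(s)\n", x$label, x$m))
  if (x$m > 0L) {
    cat(sprintf("  total signal: min %.4g, median %.4g, max %.4g\n",
                min(x$blocks$total_signal),
                stats::median(x$blocks$total_signal),
                max(x$blocks$total_signal)))
  }
  invisible(x)
}

#' Extract the vector of per-block total signals
#'
#' @param set a `block_set` from [aggregate_blocks()].
#' @return numeric vector of `total_signal` values, in block order.
#' @export
block_totals <- function(set) {
  stopifnot(inherits(set, "block_set"))
  set$blocks$total_signal
}
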