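#' @title Overlap-based evaluation against a reference peak set
#' @description Precision, recall, F1 and rank-swept precision-recall curves
#'   for comparing a called peak set to a reference set, with bedtools
#'   `intersect -u` overlap semantics: an interval counts once if it shares
#'   at least 1 bp with any interval of the other set.
#' @name pr_eval
NULL

coerce_intervals <- function(x) {
  if (inherits(x, "block_set")) return(x$blocks)
  as.data.table(x)
}

#' Directed overlap counts between two interval sets
#'
#' @param called,reference interval sets (data.frames with `chrom`, `start`,
#'   `end`, or `block_set`s), half-open coordinates.
#' @return list with `n_called_overlapping` (called intervals sharing >= 1 bp
#'   with any reference interval, each counted once) and
#'   `n_reference_overlapped` (the symmetric count).
#' @export
overlap_counts <- function(called, reference) {
  a <- coerce_intervals(called)
  b <- coerce_intervals(reference)
  list(n_called_overlapping = sum(overlaps_any(a, b)),
       n_reference_overlapped = sum(overlaps_any(b, a)))
}

#' Precision, recall and F1 of a called peak set
#'
#' Precision is the fraction of called peaks overlapped by a reference peak;
#' recall is the fraction of reference peaks overlapped by a called peak;
#' \deqn{F_1 = \frac{2 P R}{P + R}} (0 when `P + R == 0`).
#'
#' @inheritParams overlap_counts
#' @return list with `precision`, `recall`, `f1`,
#'   `n_called`, `n_reference`, `n_called_overlapping`,
#'   `n_reference_overlapped`.
#' @examples
#' called <- data.frame(chrom = "chr1", start = c(0, 20, 40, 60),
#'                      end = c(10, 30, 50, 70))
#' ref <- data.frame(chrom = "chr1", start = c(5, 25, 100, 120, 140),
#'                   end = c(15, 35, 110, 130, 150))
#' precision_recall_f1(called, ref) # P = 0.5, R = 0.4, F1 = 0.444...
#' @export
precision_recall_f1 <- function(called, reference) {
  a <- coerce_intervals(called)
  b <- coerce_intervals(reference)
  if (nrow(b) == 0L) stop("reference peak set is empty; recall is undefined")
  cnt <- overlap_counts(a, b)
  if (nrow(a) == 0L) {
    warning("called peak set is empty; precision reported as 0")
    p <- 0
  } else {
    p <- cnt$n_called_overlapping / nrow(a)
  }
  r <- cnt$n_reference_overlapped / nrow(b)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1,
       n_called = nrow(a), n_reference = nrow(b),
       n_called_overlapping = cnt$n_called_overlapping,
       n_reference_overlapped = cnt$n_reference_overlapped)
}

# For each reference interval, the maximum ranking metric among called
# intervals overlapping it (NA when none does).
ref_best_score <- function(reference, called, score) {
  n_ref <- nrow(reference)
  best <- rep(NA_real_, n_ref)
  if (n_ref == 0L || nrow(called) == 0L) return(best)
  q <- as_closed(reference)
  q[, ri := .I]
  s <- as_closed(called)
  s[, sc := score]
  setkey(s, chrom, start, end)
  ov <- foverlaps(q, s, type = "any", nomatch = NULL)
  if (nrow(ov)) {
    agg <- ov[, .(b = max(sc)), by = ri]
    best[agg$ri] <- agg$b
  }
  best
}

#' Rank-swept precision-recall curve and AUPR
#'
#' Called peaks carry a ranking metric (for this pipeline, the block total
#' signal). For every distinct metric value v, taken in descending order,
#' precision and recall are computed over the subset of called peaks with
#' metric >= v; tied metric values are grouped at one cutoff. The area under
#' the curve is the trapezoidal area over the observed (recall, precision)
#' points sorted by recall, without extrapolation to recall 0 or 1
#' (unextrapolated area is conservative and comparable across methods
#' evaluated the same way).
#'
#' @param called called peaks: a `block_set`, or a data.frame containing the
#'   score column.
#' @param reference reference peak set (non-empty).
#' @param score_col name of the ranking-metric column in `called`
#'   (default `"total_signal"`; use `"score"` for sets from [read_bed()]).
#' @param n_cutoffs optional cap on the number of cutoffs; distinct metric
#'   values are subsampled evenly (endpoints always kept). `NULL` sweeps all.
#' @return a `pr_curve`: list with `points` (a `data.table` with `cutoff`,
#'   `precision`, `recall`, descending cutoff) and `aupr`.
#' @export
pr_curve <- function(called, reference, score_col = "total_signal",
                     n_cutoffs = NULL) {
  a <- coerce_intervals(called)
  b <- coerce_intervals(reference)
  if (nrow(b) == 0L)
    stop("reference peak set is empty; a precision-recall curve is undefined")
  if (nrow(a) == 0L) stop("called peak set is empty")
  if (!score_col %in% names(a))
    stop("called set has no ranking-metric column '", score_col, "'")
  score <- as.numeric(a[[score_col]])
  if (anyNA(score)) stop("ranking metric contains missing values")

  flags <- overlaps_any(a, b)
  ord <- order(score, decreasing = TRUE)
  s_sorted <- score[ord]
  cum_tp <- cumsum(flags[ord])
  grp_end <- c(which(diff(s_sorted) != 0), length(s_sorted))
  if (!is.null(n_cutoffs) && is.finite(n_cutoffs) &&
      n_cutoffs < length(grp_end)) {
    idx <- unique(round(seq(1L, length(grp_end), length.out = n_cutoffs)))
    grp_end <- grp_end[idx]
  }
  cutoffs <- s_sorted[grp_end]
  precision <- cum_tp[grp_end] / grp_end

  best <- ref_best_score(b, a, score)
  best <- best[!is.na(best)]
  recall <- vapply(cutoffs, function(v) sum(best >= v), numeric(1L)) / nrow(b)

  points <- data.table(cutoff = cutoffs, precision = precision,
                       recall = recall)
  if (nrow(points) == 1L) {
    warning("constant ranking metric: single-point curve, ",
            "aupr = precision * recall")
    aupr <- points$precision * points$recall
  } else {
    o <- order(points$recall, points$precision)
    r <- points$recall[o]
    p <- points$precision[o]
    aupr <- sum(diff(r) * (p[-1L] + p[-length(p)]) / 2)
  }
  structure(list(points = points, aupr = aupr,
                 n_called = nrow(a), n_reference = nrow(b)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d cutoff(s), %d called vs %d reference; AUPR = %.4g\n",
              nrow(x$points), x$n_called, x$n_reference, x$aupr))
  invisible(x)
}
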