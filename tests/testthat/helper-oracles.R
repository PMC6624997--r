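# Independent brute-force oracles and random-instance generators.
# These deliberately avoid the package's own interval machinery: the block
# oracle materializes per-base coverage, the threshold oracle loops over
# candidates, and the overlap oracle does an all-pairs scan.

# Random sorted, non-overlapping nonzero bedgraph on small genomes, built by
# run-length-encoding random per-base coverage so that adjacent rows with
# differing signal (the interesting case for block aggregation) are common.
random_bedgraph <- function(glen = 1000L, p_zero = 0.7,
                            chroms = c("chr1", "chr2"),
                            integer_signal = TRUE) {
  rows <- lapply(chroms, function(ch) {
    vals <- if (integer_signal) 0:4 else c(0, stats::runif(4, 0.1, 10))
    cov <- sample(vals, glen, replace = TRUE,
                  prob = c(p_zero, rep((1 - p_zero) / 4, 4)))
    # smear into short runs so rows are wider than 1 bp on average
    reps <- sample(1:5, glen, replace = TRUE)
    cov <- rep(cov, reps)[seq_len(glen)]
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 0
    data.frame(chrom = ch, start = starts[keep] - 1L, end = ends[keep],
               signal = r$values[keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Per-base brute-force block finder: coverage array -> maximal nonzero runs.
brute_blocks <- function(bg, glen = 1000L) {
  out <- lapply(split(bg, bg$chrom), function(x) {
    cov <- numeric(glen)
    for (i in seq_len(nrow(x)))
      cov[(x$start[i] + 1L):x$end[i]] <- x$signal[i]
    r <- rle(cov > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    data.frame(
      chrom = rep(x$chrom[1L], length(runs)),
      start = starts[runs] - 1L,
      end = ends[runs],
      total_signal = vapply(runs, function(j)
        sum(cov[starts[j]:ends[j]]), numeric(1L)),
      max_signal = vapply(runs, function(j)
        max(cov[starts[j]:ends[j]]), numeric(1L)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Exhaustive scan over all distinct totals for (f_max, t_stringent),
# tracking the smallest maximizer with strict improvement only.
brute_f_best <- function(rt, st) {
  cand <- sort(unique(c(0, rt, st)))
  best_f <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    p_t <- sum(rt > t) / length(rt)
    p_c <- sum(st > t) / length(st)
    if (p_t + p_c == 0) next
    f <- p_t / (p_t + p_c)
    if (f > best_f) {
      best_f <- f
      best_t <- t
    }
  }
  list(f_max = best_f, t_stringent = best_t)
}

# All-pairs half-open overlap flags for each row of a against b.
brute_overlap_flags <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1L))
}

# Random (possibly overlapping) interval set for evaluation tests.
random_interval_set <- function(n, glen = 10000L, wmax = 400L,
                                chroms = c("chr1", "chr2")) {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(glen - wmax, n, replace = TRUE)
  w <- sample.int(wmax, n, replace = TRUE)
  data.frame(chrom = ch, start = s, end = s + w)[order(ch, s), , drop = FALSE]
}
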