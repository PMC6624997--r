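# Half-open interval overlap helpers shared by the caller and the evaluator.
# data.table::foverlaps works on closed intervals; integer half-open
# [start, end) maps exactly onto closed [start, end - 1].

as_closed <- function(x) {
  data.table(chrom = as.character(x$chrom),
             start = as.integer(x$start),
             end = as.integer(x$end) - 1L)
}

# For each row of `query`, TRUE iff it shares >= 1 bp with any row of
# `subject` (same chromosome, half-open coordinates).
overlaps_any <- function(query, subject) {
  nq <- nrow(query)
  if (nq == 0L) return(logical(0L))
  if (nrow(subject) == 0L) return(rep(FALSE, nq))
  q <- as_closed(query)
  s <- as_closed(subject)
  setkey(s, chrom, start, end)
  hits <- foverlaps(q, s, type = "any", which = TRUE, nomatch = NULL)
  out <- rep(FALSE, nq)
  out[unique(hits$xid)] <- TRUE
  out
}
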