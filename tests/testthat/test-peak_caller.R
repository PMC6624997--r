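make_blocks <- function(totals, chrom = "chr1", width = 100L, gap = 50L) {
  n <- length(totals)
  start <- (width + gap) * (seq_len(n) - 1L)
  iv <- data.frame(chrom = chrom, start = start, end = start + width,
                   signal = totals / width)
  aggregate_blocks(iv)
}

test_that("filter_by_threshold keeps exactly the blocks above t", {
  bs <- make_blocks(c(50, 60, 10, 5))
  expect_equal(block_totals(filter_by_threshold(bs, 12)), c(50, 60))
  expect_equal(filter_by_threshold(bs, 0)$m, 4L)
  expect_warning(out <- filter_by_threshold(bs, 60), "no signal block")
  expect_equal(out$m, 0L)
})

test_that("control-overlap removal respects threshold gate and half-open ends", {
  target <- aggregate_blocks(data.frame(chrom = "chr1", start = 100L,
                                        end = 200L, signal = 1))
  ctrl_hit <- aggregate_blocks(data.frame(chrom = "chr1", start = 150L,
                                          end = 250L, signal = 1),
                               label = "control")
  out <- remove_control_overlaps(target, ctrl_hit, t = 50)
  expect_equal(out$peaks$m, 0L)
  expect_equal(out$removed, 1L)
  # same geometry but the control block does not pass the threshold
  out2 <- remove_control_overlaps(target, ctrl_hit, t = 100)
  expect_equal(out2$peaks$m, 1L)
  # bookended intervals share no base under half-open coordinates
  ctrl_book <- aggregate_blocks(data.frame(chrom = "chr1", start = 200L,
                                           end = 300L, signal = 1),
                                label = "control")
  expect_equal(remove_control_overlaps(target, ctrl_book, t = 0)$peaks$m, 1L)
})

test_that("planted fixture: stringent call recovers the truth cleanly", {
  pair <- simulate_pair(sim_preset("tf", seed = 7))
  res <- call_peaks(pair$target, pair$igg, mode = "stringent", norm = FALSE,
                    quiet = TRUE)
  hit <- overlap_counts(res$peaks, pair$truth)
  expect_gte(hit$n_reference_overlapped, 18L)
  expect_equal(res$n_control_filtered, 0L)
  expect_lte(res$fdr$value, 0.1)
  # pipeline conservation
  expect_equal(res$peaks$m + res$n_below_threshold + res$n_control_filtered,
               res$n_input_blocks)
})

test_that("null fixture: almost no target blocks survive stringent calling", {
  pair <- simulate_pair(sim_preset("null", seed = 11))
  res <- suppressWarnings(
    call_peaks(pair$target, pair$igg, norm = FALSE, quiet = TRUE))
  expect_lte(res$peaks$m / res$n_input_blocks, 0.05)
})

test_that("global mode retains the ceiling-adjusted top fraction", {
  pair <- simulate_pair(sim_preset("tf", seed = 3))
  res <- call_peaks(pair$target, 0.01, quiet = TRUE)
  expect_equal(res$mode, "global")
  expect_equal(res$n_control_filtered, 0L)
  expect_null(res$fdr)
  totals <- block_totals(aggregate_blocks(pair$target))
  k <- ceiling(0.01 * length(totals))
  expect_lte(res$peaks$m, k)
  expect_equal(res$threshold, sort(totals, decreasing = TRUE)[k + 1L])
})

test_that("relaxed peak set contains the stringent peak set", {
  for (seed in c(2, 9)) {
    pair <- simulate_pair(sim_preset("tf", seed = seed))
    s <- call_peaks(pair$target, pair$igg, mode = "stringent", norm = FALSE,
                    quiet = TRUE)
    r <- call_peaks(pair$target, pair$igg, mode = "relaxed", norm = FALSE,
                    quiet = TRUE)
    expect_lte(r$threshold, s$threshold)
    key_s <- with(s$peaks$blocks, paste(chrom, start, end))
    key_r <- with(r$peaks$blocks, paste(chrom, start, end))
    expect_true(all(key_s %in% key_r))
  }
})

test_that("normalization rescales a depth-shifted control onto the target", {
  pair <- simulate_pair(sim_preset("tf", seed = 19))
  # emulate a control sequenced at half depth: same blocks, half the signal
  igg_half <- transform(pair$igg, signal = signal / 2)
  res_matched <- call_peaks(pair$target, pair$igg, norm = FALSE, quiet = TRUE)
  res_norm <- call_peaks(pair$target, igg_half, norm = TRUE, quiet = TRUE)
  expect_equal(res_norm$scaling_factor, 2, tolerance = 1e-6)
  expect_equal(res_norm$peaks$blocks$start, res_matched$peaks$blocks$start)
  expect_equal(res_norm$threshold, res_matched$threshold, tolerance = 1e-6)
})

test_that("pipeline is deterministic and writes the expected files", {
  pair <- simulate_pair(sim_preset("tf", seed = 4))
  dir <- withr::local_tempdir()
  tgt <- file.path(dir, "t.bedgraph")
  ctl <- file.path(dir, "c.bedgraph")
  write_bedgraph(pair$target, tgt)
  write_bedgraph(pair$igg, ctl)
  p1 <- file.path(dir, "run1")
  p2 <- file.path(dir, "run2")
  call_peaks(tgt, ctl, norm = FALSE, output_prefix = p1, quiet = TRUE)
  call_peaks(tgt, ctl, norm = FALSE, output_prefix = p2, quiet = TRUE)
  f1 <- paste0(p1, ".stringent.bed")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(paste0(p2, ".stringent.bed")))
})

test_that("input errors are informative", {
  expect_error(call_peaks(data.frame(chrom = character(), start = integer(),
                                     end = integer(), signal = numeric()),
                          0.1),
               "no nonzero signal")
  pair <- simulate_pair(sim_preset("tf", seed = 1))
  expect_error(call_peaks(pair$target, 1.5), "\\(0, 1\\)")
  expect_error(call_peaks(file.path(tempdir(), "missing.bg"), 0.1),
               "not found")
})
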