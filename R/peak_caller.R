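#' Filter signal blocks by a total-signal threshold
#'
#' Retains exactly the blocks with `total_signal > t` (strict inequality,
#' consistent with curve construction and the empirical FDR), preserving
#' order. Warns when nothing survives a positive input.
#'
#' @param blocks a `block_set`.
#' @param t threshold (>= 0).
#' @return a `block_set` of the retained blocks.
#' @export
filter_by_threshold <- function(blocks, t) {
  stopifnot(inherits(blocks, "block_set"), is.numeric(t), length(t) == 1L,
            t >= 0)
  kept <- blocks$blocks[total_signal > t]
  if (nrow(kept) == 0L && blocks$m > 0L)
    warning("no signal block exceeds threshold ", format(t))
  new_block_set(kept, blocks$label)
}

#' Remove target peaks overlapping above-threshold control blocks
#'
#' Spurious target peaks can arise at repeated regions or recurrent
#' false-positive sites that also accumulate control (IgG) signal. A retained
#' target peak is therefore removed when it shares at least 1 bp (half-open
#' overlap) with any control block whose (scaled) total also exceeds the
#' threshold.
#'
#' @param target_peaks `block_set` of threshold-passing target blocks.
#' @param control_blocks `block_set` of control blocks; `total_signal` must
#'   already be on the target scale (multiplied by the scaling factor) when
#'   normalization is in use.
#' @param t the threshold in use.
#' @return list with `peaks` (the surviving `block_set`) and `removed`
#'   (number of peaks filtered out).
#' @export
remove_control_overlaps <- function(target_peaks, control_blocks, t) {
  stopifnot(inherits(target_peaks, "block_set"),
            inherits(control_blocks, "block_set"))
  above <- control_blocks$blocks[total_signal > t]
  hit <- overlaps_any(target_peaks$blocks, above)
  list(peaks = new_block_set(target_peaks$blocks[!hit], target_peaks$label),
       removed = sum(hit))
}

#' Call peaks from target (and control) coverage
#'
#' The full pipeline: read the bedgraph(s), aggregate signal blocks, scale
#' the control onto the target (normalized mode), build the F(t) selection
#' curve, pick the threshold for the requested mode, retain target blocks
#' exceeding it, drop those overlapping above-threshold control blocks, and
#' optionally write the result as a 6-column BED file named
#' `<prefix>.<mode>.bed`.
#'
#' With a numeric `control` in (0, 1) the pipeline runs in control-free
#' global mode: the threshold is the [global_threshold()] quantile of the
#' target totals, and no overlap filtering or empirical FDR applies.
#'
#' @param target target bedgraph: a file path or a data.frame of intervals.
#' @param control IgG control bedgraph (path or data.frame), or a single
#'   numeric in (0, 1) for global-threshold mode.
#' @param mode `"stringent"` (threshold at the maximum of F, the default) or
#'   `"relaxed"` (threshold at the F-space midpoint between maximum and
#'   knee). Ignored in global mode.
#' @param norm scale control totals by the density-peak ratio before
#'   thresholding (the default, appropriate when target and control depths
#'   differ); set `FALSE` for depth-matched or externally calibrated pairs.
#' @param output_prefix when non-`NULL`, peaks are written to
#'   `<output_prefix>.<mode>.bed`.
#' @param f_variant F-curve form, see [compute_f_curve()].
#' @param merge_gap passed to [aggregate_blocks()].
#' @param enrichment_z degenerate-input safeguard for control mode: the
#'   curve's threshold is trusted only when some candidate's F exceeds the
#'   no-enrichment baseline 0.5 by more than `enrichment_z` binomial standard
#'   errors of the remaining-block count. When target and control are
#'   statistically indistinguishable (no real enrichment) the F maximizer is
#'   a noise artifact that can sit anywhere in the bulk of the distribution;
#'   in that case the pipeline falls back to the conservative
#'   control-maximum threshold, retaining only target blocks that exceed
#'   every (scaled) control block.
#' @param quiet suppress per-stage log messages.
#' @return a `peak_call`: list with `peaks` (retained `block_set`),
#'   `threshold`, `mode`, `threshold_source` (`"curve"`, `"control_max"` for
#'   the degenerate-input fallback, or `"quantile"`), `scaling_factor`,
#'   `fdr` (`NULL` in global mode), `n_input_blocks`, `n_below_threshold`,
#'   `n_control_filtered`, `curve` (`NULL` in global mode), `output_file`.
#' @examples
#' tgt <- data.frame(chrom = "chr1", start = c(0L, 100L, 110L),
#'                   end = c(50L, 110L, 160L), signal = c(1, 8, 6))
#' ctl <- data.frame(chrom = "chr1", start = c(10L, 300L),
#'                   end = c(60L, 350L), signal = c(1, 1))
#' call_peaks(tgt, ctl, norm = FALSE, quiet = TRUE)$peaks$blocks
#' @export
call_peaks <- function(target, control, mode = c("stringent", "relaxed"),
                       norm = TRUE, output_prefix = NULL,
                       f_variant = c("remaining", "printed"),
                       merge_gap = 0, enrichment_z = 4, quiet = FALSE) {
  mode <- match.arg(mode)
  f_variant <- match.arg(f_variant)
  say <- function(...) if (!quiet) message(...)

  tgt <- if (is.character(target)) read_bedgraph(target) else
    as.data.table(target)
  if (nrow(tgt) == 0L)
    stop("target bedgraph contains no nonzero signal")
  tb <- aggregate_blocks(tgt, merge_gap = merge_gap, label = "target")
  rt <- block_totals(tb)

  global_q <- is.numeric(control) && length(control) == 1L
  if (global_q) {
    if (control <= 0 || control >= 1)
      stop("numeric control threshold must lie in (0, 1)")
    say(sprintf("target: %d signal blocks; global mode (top %.4g fraction)",
                tb$m, control))
    thr <- global_threshold(rt, control)
    kept <- filter_by_threshold(tb, thr)
    say(sprintf("threshold = %.6g; retained %d of %d blocks",
                thr, kept$m, tb$m))
    res <- structure(list(
      peaks = kept, threshold = thr, mode = "global",
      threshold_source = "quantile",
      scaling_factor = 1, fdr = NULL,
      n_input_blocks = tb$m, n_below_threshold = tb$m - kept$m,
      n_control_filtered = 0L, curve = NULL, output_file = NULL
    ), class = "peak_call")
  } else {
    ctl <- if (is.character(control)) read_bedgraph(control) else
      as.data.table(control)
    if (nrow(ctl) == 0L)
      stop("control bedgraph contains no nonzero signal; supply a numeric ",
           "threshold in (0, 1) for control-free calling")
    cb <- aggregate_blocks(ctl, merge_gap = merge_gap, label = "control")
    st <- block_totals(cb)
    say(sprintf("target: %d signal blocks; control: %d signal blocks",
                tb$m, cb$m))
    scaling <- 1
    if (norm) {
      nr <- normalize_control(rt, st)
      scaling <- nr$scaling_factor
      say(sprintf("normalization: target mode %.6g / control mode %.6g -> scaling factor %.6g",
                  nr$target_mode, nr$control_mode, scaling))
    }
    st_scaled <- st * scaling
    curve <- compute_f_curve(rt, st_scaled, variant = f_variant)
    if (mode == "relaxed") curve <- select_relaxed(curve)
    if (curve_has_enrichment(curve, z = enrichment_z)) {
      threshold_source <- "curve"
      thr <- if (mode == "relaxed") curve$t_relaxed else curve$t_stringent
      # the artifact filter is always gated at the stringent threshold: a
      # permissive relaxed threshold should admit more target blocks, not
      # discard more of them over marginal IgG blocks -- this keeps the
      # relaxed peak set a superset of the stringent one
      t_gate <- curve$t_stringent
      say(sprintf("%s threshold = %.6g (f_max = %.4g)", mode, thr,
                  curve$f_max))
    } else {
      # the curve never rises credibly above the no-enrichment baseline:
      # retain only blocks exceeding the entire (scaled) control distribution
      threshold_source <- "control_max"
      thr <- max(st_scaled)
      t_gate <- thr
      say(sprintf(
        "no credible target enrichment in the threshold curve (f_max = %.4g); falling back to the conservative control-maximum threshold %.6g",
        curve$f_max, thr))
    }
    kept <- filter_by_threshold(tb, thr)
    cb_scaled <- new_block_set(
      copy(cb$blocks)[, total_signal := total_signal * scaling], "control")
    ov <- remove_control_overlaps(kept, cb_scaled, t_gate)
    fdr <- empirical_fdr(rt, st_scaled, thr)
    say(sprintf(
      "retained %d of %d target blocks (%d below threshold, %d removed by control overlap); empirical FDR = %.4g",
      ov$peaks$m, tb$m, tb$m - kept$m, ov$removed, fdr$value))
    res <- structure(list(
      peaks = ov$peaks, threshold = thr, mode = mode,
      threshold_source = threshold_source,
      scaling_factor = scaling, fdr = fdr,
      n_input_blocks = tb$m, n_below_threshold = tb$m - kept$m,
      n_control_filtered = ov$removed, curve = curve, output_file = NULL
    ), class = "peak_call")
  }

  if (!is.null(output_prefix)) {
    path <- paste0(output_prefix, ".", res$mode, ".bed")
    write_peaks_bed(path, res$peaks)
    res$output_file <- path
    say("wrote ", path)
  }
  res
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> mode = %s, threshold = %.6g\n", x$mode, x$threshold))
  cat(sprintf("  %d peak(s) from %d input block(s) (%d below threshold, %d control-overlap filtered)\n",
              x$peaks$m, x$n_input_blocks, x$n_below_threshold,
              x$n_control_filtered))
  if (!is.null(x$fdr))
    cat(sprintf("  scaling factor = %.6g, empirical FDR = %.4g\n",
                x$scaling_factor, x$fdr$value))
  if (!is.null(x$output_file)) cat("  output:", x$output_file, "\n")
  invisible(x)
}

# Machine-readable one-object summary of a peak_call (used by the CLI).
peak_call_summary <- function(x) {
  list(mode = x$mode,
       threshold = x$threshold,
       scaling_factor = x$scaling_factor,
       n_input_blocks = x$n_input_blocks,
       n_peaks = x$peaks$m,
       n_below_threshold = x$n_below_threshold,
       n_control_filtered = x$n_control_filtered,
       empirical_fdr = if (is.null(x$fdr)) NULL else x$fdr$value,
       output_file = x$output_file)
}
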