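#' @title Seeded synthetic CUT&RUN fixtures
#' @description Generator of paired target/IgG bedgraphs with known truth,
#'   emulating the sparse-background regime of CUT&RUN: isolated background
#'   fragments scattered over a mostly zero-coverage genome, plus planted
#'   enriched intervals (narrow peaks, broad domains) in the target. Target
#'   and IgG background follow the identical law, so a depth-matched pair is
#'   produced by construction. Everything is reproducible from the seed.
#' @name synthetic_cutrun
NULL

#' Simulation configuration
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param n_peaks number of planted narrow enriched intervals (target only).
#' @param peak_width length-2 numeric, uniform sampling bounds (bp) for
#'   planted peak widths.
#' @param peak_fragments Poisson mean fragment count per planted peak.
#' @param background_fragments_per_mb Poisson mean count of sparse background
#'   fragments per megabase, applied identically to target and IgG.
#' @param fragment_length a single value for fixed-length fragments (the
#'   default: each preset uses the characteristic protected-fragment size of
#'   its target class, so background block totals are clean multiples of the
#'   fragment length), or a length-2 vector of (min, max) bounds, in which
#'   case lengths are drawn from a truncated normal centered between the
#'   bounds (fragment sizes concentrate around the protected length rather
#'   than spreading uniformly).
#' @param broad_domains optional data.frame (`chrom`, `start`, `end`, `fold`)
#'   of planted broad domains; `fold` is fragment density relative to
#'   background, so a domain receives on average
#'   `fold * background_density * width` fragments.
#' @param null_mode draw the target exactly as the IgG control (background
#'   only, no planted enrichment); requires `n_peaks = 0` and no domains.
#' @param seed integer RNG seed; the pair is a deterministic function of the
#'   configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome = c(chr1 = 3e6, chr2 = 2e6),
                       n_peaks = 20L,
                       peak_width = c(200, 700),
                       peak_fragments = 100,
                       background_fragments_per_mb = 100,
                       fragment_length = 120,
                       broad_domains = NULL,
                       null_mode = FALSE,
                       seed = 1L) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))) ||
      any(genome <= 0))
    stop("genome must be a named vector of positive chromosome lengths")
  if (length(peak_width) == 1L) peak_width <- rep(peak_width, 2L)
  if (length(fragment_length) == 1L)
    fragment_length <- rep(fragment_length, 2L)
  stopifnot(length(peak_width) == 2L, peak_width[1L] <= peak_width[2L],
            length(fragment_length) == 2L,
            fragment_length[1L] <= fragment_length[2L],
            fragment_length[1L] >= 1)
  if (!is.null(broad_domains)) {
    broad_domains <- as.data.table(broad_domains)
    need <- c("chrom", "start", "end", "fold")
    if (!all(need %in% names(broad_domains)))
      stop("broad_domains needs columns chrom, start, end, fold")
    if (!all(broad_domains$chrom %in% names(genome)) ||
        any(broad_domains$start < 0) ||
        any(broad_domains$end > genome[broad_domains$chrom]))
      stop("broad domains fall outside the genome")
  }
  if (null_mode && (n_peaks > 0L || !is.null(broad_domains)))
    stop("null_mode draws target and control from the same background law; ",
         "set n_peaks = 0 and no broad_domains")
  # feasibility: planted intervals (with spacing margin) must fit
  margin <- 2 * fragment_length[2L] + 1000
  demand <- n_peaks * (peak_width[2L] + margin) +
    if (is.null(broad_domains)) 0 else
      sum(broad_domains$end - broad_domains$start)
  if (demand > 0.5 * sum(genome))
    stop("infeasible configuration: planted intervals exceed genome capacity")
  structure(list(genome = genome, n_peaks = as.integer(n_peaks),
                 peak_width = peak_width, peak_fragments = peak_fragments,
                 background_fragments_per_mb = background_fragments_per_mb,
                 fragment_length = fragment_length,
                 broad_domains = broad_domains, null_mode = null_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset simulation configurations
#'
#' * `"tf"` - 20 narrow transcription-factor-like peaks (200-700 bp, ~100
#'   fragments each) of short fixed-length fragments over sparse background.
#' * `"histone"` - 10 multi-kilobase histone-mark-like regions (2-10 kb,
#'   nucleosomal fragment length).
#' * `"broad"` - a single contiguous 50 kb domain (fragment density 1000x
#'   background) for domain-coherence checks.
#' * `"null"` - background only, target exchangeable with IgG: the synthetic
#'   analog of profiling an unexpressed factor, where every called peak is a
#'   false positive.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("tf", "histone", "broad", "null"),
                       seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    tf = list(),
    histone = list(n_peaks = 10L, peak_width = c(2000, 10000),
                   peak_fragments = 400, fragment_length = 170),
    broad = list(genome = c(chr1 = 2e6), n_peaks = 0L,
                 fragment_length = 170,
                 broad_domains = data.frame(chrom = "chr1", start = 1e6,
                                            end = 1.05e6, fold = 1000)),
    null = list(n_peaks = 0L, null_mode = TRUE)
  )
  args$seed <- seed
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Run-length-encoded coverage from fragment spans
#'
#' Accumulates exact per-base depth over a set of (half-open) fragment
#' intervals and emits it as bedgraph rows: adjacent runs of equal depth are
#' merged and zero-depth positions are omitted.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`.
#' @return a bedgraph `data.table` (`chrom`, `start`, `end`, `signal`),
#'   sorted.
#' @examples
#' coverage_from_fragments(
#'   data.frame(chrom = "chr1", start = c(0L, 5L), end = c(10L, 15L)))
#' @export
coverage_from_fragments <- function(fragments) {
  f <- as.data.table(fragments)
  if (nrow(f) == 0L) return(empty_bedgraph())
  ev <- rbind(
    f[, .(chrom = as.character(chrom), pos = as.integer(start), d = 1L)],
    f[, .(chrom = as.character(chrom), pos = as.integer(end), d = -1L)]
  )
  ev <- ev[, .(d = sum(d)), by = .(chrom, pos)]
  setorder(ev, chrom, pos)
  out <- ev[, {
    depth <- cumsum(d)
    s <- pos[-.N]
    e <- pos[-1L]
    dep <- depth[-.N]
    r <- rle(dep)
    iend <- cumsum(r$lengths)
    ibeg <- iend - r$lengths + 1L
    .(start = s[ibeg], end = e[iend], signal = as.numeric(r$values))
  }, by = chrom]
  out <- out[signal > 0]
  setorder(out, chrom, start)
  out[]
}

# Paired-end fragment sizes cluster around a characteristic protected length
# rather than spreading uniformly: lengths are drawn from a normal centered
# between the bounds (sd = range/4) and truncated to [min, max] by resampling.
draw_fragment_lengths <- function(k, law) {
  if (law[1L] == law[2L]) return(rep(as.integer(law[1L]), k))
  mu <- mean(law)
  sdev <- (law[2L] - law[1L]) / 4
  out <- round(stats::rnorm(k, mu, sdev))
  bad <- which(out < law[1L] | out > law[2L])
  while (length(bad)) {
    out[bad] <- round(stats::rnorm(length(bad), mu, sdev))
    bad <- bad[out[bad] < law[1L] | out[bad] > law[2L]]
  }
  as.integer(out)
}

# k fragment spans with starts uniform on [lo, hi - L] of one chromosome
uniform_fragments <- function(k, chrom, lo, hi, len_law) {
  if (k == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  len <- draw_fragment_lengths(k, len_law)
  start <- as.integer(floor(runif(k, lo, pmax(lo + 1, hi - len))))
  data.table(chrom = rep(chrom, k), start = start,
             end = start + len)
}

background_fragments <- function(config) {
  g <- config$genome
  dens <- config$background_fragments_per_mb / 1e6
  k <- rpois(length(g), dens * g)
  out <- vector("list", length(g))
  for (i in seq_along(g)) {
    out[[i]] <- uniform_fragments(k[i], names(g)[i], 0, g[i],
                                  config$fragment_length)
  }
  rbindlist(out)
}

place_planted <- function(config) {
  g <- config$genome
  margin <- config$fragment_length[2L] + 500
  placed <- if (is.null(config$broad_domains))
    data.table(chrom = character(), start = integer(), end = integer(),
               name = character(), fold = numeric())
  else {
    bd <- as.data.table(config$broad_domains)
    data.table(chrom = as.character(bd$chrom), start = as.integer(bd$start),
               end = as.integer(bd$end),
               name = sprintf("domain_%d", seq_len(nrow(bd))),
               fold = as.numeric(bd$fold))
  }
  bg_dens <- config$background_fragments_per_mb / 1e6
  for (i in seq_len(config$n_peaks)) {
    ok <- FALSE
    for (attempt in 1:1000) {
      ci <- sample.int(length(g), 1L, prob = g)
      w <- as.integer(floor(runif(1L, config$peak_width[1L],
                                  config$peak_width[2L] + 1)))
      if (g[ci] < w + 2 * margin) next
      s <- as.integer(floor(runif(1L, margin, g[ci] - w - margin)))
      cand <- data.table(chrom = names(g)[ci], start = s, end = s + w)
      # keep planted intervals separated so truth regions stay distinct
      pad <- copy(placed)[, `:=`(start = pmax(0L, start - as.integer(margin)),
                                 end = end + as.integer(margin))]
      if (!any(overlaps_any(cand, pad))) {
        fold <- config$peak_fragments / (w * bg_dens)
        placed <- rbind(placed,
                        data.table(chrom = names(g)[ci], start = s,
                                   end = s + w,
                                   name = sprintf("peak_%d", i),
                                   fold = fold))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place planted peak ", i, "; genome too crowded")
  }
  setorder(placed, chrom, start)
  placed[]
}

#' Simulate a paired target/IgG fixture with known truth
#'
#' Background fragments are scattered uniformly (Poisson counts) over the
#' genome, independently for target and IgG but under the identical law.
#' Planted peaks receive Poisson(`peak_fragments`) target fragments placed
#' uniformly within the planted interval; broad domains receive fragments at
#' `fold` times the background density. Coverage is accumulated exactly per
#' base and emitted as merged nonzero bedgraph rows.
#'
#' The caller's RNG state is saved and restored; the result depends only on
#' the configuration (including its seed).
#'
#' @param config a [sim_config()].
#' @return a `sim_pair`: list with `target` and `igg` bedgraph `data.table`s,
#'   `truth` (planted intervals with `name` and expected `fold` enrichment),
#'   and `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  truth <- place_planted(config)
  bg_dens <- config$background_fragments_per_mb / 1e6

  planted_frags <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    w <- truth$end[i] - truth$start[i]
    mean_k <- if (startsWith(truth$name[i], "domain"))
      truth$fold[i] * bg_dens * w else config$peak_fragments
    k <- rpois(1L, mean_k)
    planted_frags[[i]] <- uniform_fragments(k, truth$chrom[i],
                                            truth$start[i], truth$end[i],
                                            config$fragment_length)
  }
  target_frags <- rbind(rbindlist(planted_frags),
                        background_fragments(config))
  igg_frags <- background_fragments(config)

  structure(list(target = coverage_from_fragments(target_frags),
                 igg = coverage_from_fragments(igg_frags),
                 truth = truth,
                 config = config),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf(
    "<sim_pair> seed %d: %d target rows, %d IgG rows, %d truth interval(s)\n",
    x$config$seed, nrow(x$target), nrow(x$igg), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated pair to disk
#'
#' Writes `<prefix>.target.bedgraph`, `<prefix>.igg.bedgraph`,
#' `<prefix>.truth.bed` (5-column: name in column 4, expected fold
#' enrichment as the score in column 5) and `<prefix>.config.json`.
#'
#' @param pair a `sim_pair` from [simulate_pair()].
#' @param prefix output path prefix.
#' @return named character vector of the four paths, invisibly.
#' @export
write_sim_pair <- function(pair, prefix) {
  stopifnot(inherits(pair, "sim_pair"))
  paths <- c(target = paste0(prefix, ".target.bedgraph"),
             igg = paste0(prefix, ".igg.bedgraph"),
             truth = paste0(prefix, ".truth.bed"),
             config = paste0(prefix, ".config.json"))
  write_bedgraph(pair$target, paths[["target"]])
  write_bedgraph(pair$igg, paths[["igg"]])
  tr <- pair$truth
  writeLines(
    if (nrow(tr)) paste(tr$chrom, tr$start, tr$end, tr$name,
                        fmt_num(tr$fold), sep = "\t") else character(),
    paths[["truth"]])
  cfg <- pair$config
  cfg_list <- list(genome = as.list(cfg$genome), n_peaks = cfg$n_peaks,
                   peak_width = cfg$peak_width,
                   peak_fragments = cfg$peak_fragments,
                   background_fragments_per_mb =
                     cfg$background_fragments_per_mb,
                   fragment_length = cfg$fragment_length,
                   broad_domains = if (is.null(cfg$broad_domains)) NULL else
                     as.data.frame(cfg$broad_domains),
                   null_mode = cfg$null_mode, seed = cfg$seed)
  jsonlite::write_json(cfg_list, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
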