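#' @title Empirical threshold selection on block totals
#' @description The threshold machinery: density-peak normalization of the
#'   control, the F(t) selection curve over candidate thresholds, stringent
#'   and relaxed threshold selection, control-free global quantile thresholds,
#'   and the empirical FDR. Retention is strictly greater-than (`total > t`)
#'   everywhere: curve construction, filtering, and FDR all use the same rule.
#' @name threshold_model
NULL

# Mode of a sample located via Gaussian KDE, Silverman (nrd0) bandwidth,
# on a 512-point uniform grid over [0, max(x)], then refined by evaluating
# the exact KDE at the observed values within one grid step of the grid
# argmax. The refinement makes the located mode independent of the grid
# resolution, which matters when a few very large block totals stretch the
# grid while the background mass is concentrated (possibly heavily tied) far
# below. A single-valued sample is its own mode.
kde_mode <- function(x, n_grid = 512L, bw = "nrd0") {
  ux <- sort(unique(x))
  if (length(ux) == 1L) return(ux)
  d <- stats::density(x, bw = bw, n = n_grid, from = 0, to = max(x))
  x0 <- d$x[which.max(d$y)]
  step <- d$x[2L] - d$x[1L]
  cand <- ux[ux >= x0 - step & ux <= x0 + step]
  if (!length(cand)) return(x0)
  dens <- vapply(cand, function(g) sum(stats::dnorm((x - g) / d$bw)),
                 numeric(1L))
  cand[which.max(dens)]
}

#' Normalize control block totals to the target
#'
#' Background block totals in target and control data concentrate around a
#' typical single-fragment value; their ratio reflects the relative depth of
#' the two libraries. The density peak (mode) of each total-signal
#' distribution is located by kernel density estimation and the control is
#' brought onto the target scale by the scaling factor
#' `target_mode / control_mode`. The caller multiplies every control total by
#' this factor before curve construction and overlap filtering.
#'
#' @param target_totals,control_totals positive numeric vectors of block
#'   total signals.
#' @param n_grid,bw KDE evaluation grid size and bandwidth rule passed to
#'   [stats::density()].
#' @return list with `scaling_factor`, `target_mode`, `control_mode`.
#' @export
normalize_control <- function(target_totals, control_totals,
                              n_grid = 512L, bw = "nrd0") {
  if (!length(target_totals) || !length(control_totals))
    stop("normalization requires both datasets")
  if (any(target_totals <= 0) || any(control_totals <= 0))
    stop("block totals must be positive")
  tm <- kde_mode(as.numeric(target_totals), n_grid, bw)
  cm <- kde_mode(as.numeric(control_totals), n_grid, bw)
  list(scaling_factor = tm / cm, target_mode = tm, control_mode = cm)
}

#' Compute the threshold selection curve F(t)
#'
#' For every candidate threshold t (0 and every distinct observed block total
#' from either dataset -- F is a step function that only changes at observed
#' totals, so this grid is exact), let `pT(t)` be the fraction of target
#' blocks with total > t and `pC(t)` the same for the (already scaled)
#' control. The canonical curve is
#' \deqn{F(t) = pT(t) / (pT(t) + pC(t)),}
#' the fraction of target blocks out of all blocks remaining above t.
#' Candidates where no block remains are excluded. The stringent threshold is
#' the smallest candidate attaining the maximum of F (smallest t maximizes
#' recall at equal F).
#'
#' `variant = "printed"` selects an alternative difference form based on
#' blocks *removed* at t, `F(t) = (m - #\{r > t\}) / (N - #\{pooled > t\})`
#' with a pooled target+control denominator; it is provided for comparison
#' and is not the default.
#'
#' @param target_totals numeric vector of target block totals (non-empty).
#' @param control_totals numeric vector of control block totals, already
#'   multiplied by the scaling factor when normalization is in use.
#' @param variant `"remaining"` (canonical) or `"printed"`.
#' @return a `threshold_curve`: list with `candidates`, `f_values`,
#'   `frac_target_remaining`, `frac_control_remaining`, `n_remaining`
#'   (pooled blocks above each candidate), `f_max`, `t_stringent`, `knee_f`,
#'   `t_relaxed` (`NA` until [select_relaxed()]), `t_max`, `n_target`,
#'   `n_control`, `variant`.
#' @examples
#' cv <- compute_f_curve(c(10, 10, 50, 60), c(10, 12))
#' cv$f_max       # 1
#' cv$t_stringent # 12
#' @export
compute_f_curve <- function(target_totals, control_totals,
                            variant = c("remaining", "printed")) {
  variant <- match.arg(variant)
  if (!length(target_totals))
    stop("target dataset has no signal blocks")
  if (!length(control_totals))
    stop("control dataset has no signal blocks; use global_threshold() for ",
         "control-free calling")
  rt <- sort(as.numeric(target_totals))
  st <- sort(as.numeric(control_totals))
  m <- length(rt)
  n <- length(st)
  cand <- sort(unique(c(0, rt, st)))
  n_above_t <- m - findInterval(cand, rt) # counts strictly above t
  n_above_c <- n - findInterval(cand, st)
  p_t <- n_above_t / m
  p_c <- n_above_c / n
  if (variant == "remaining") {
    keep <- (p_t + p_c) > 0
    f <- p_t[keep] / (p_t[keep] + p_c[keep])
  } else {
    pool <- sort(c(rt, st))
    n_tot <- m + n
    removed_pool <- n_tot - (n_tot - findInterval(cand, pool))
    keep <- removed_pool > 0
    f <- (m - n_above_t[keep]) / removed_pool[keep]
  }
  imax <- which.max(f) # first index = smallest candidate attaining f_max
  structure(list(
    candidates = cand[keep],
    f_values = f,
    frac_target_remaining = p_t[keep],
    frac_control_remaining = p_c[keep],
    n_remaining = n_above_t[keep] + n_above_c[keep],
    f_max = f[imax],
    t_stringent = cand[keep][imax],
    knee_f = NA_real_,
    t_relaxed = NA_real_,
    t_max = max(cand),
    n_target = m,
    n_control = n,
    variant = variant
  ), class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "<threshold_curve> %d candidates on [0, %.4g] (%s variant)\n",
    length(x$candidates), x$t_max, x$variant))
  cat(sprintf("  f_max = %.4g at t_stringent = %.6g\n", x$f_max, x$t_stringent))
  if (!is.na(x$t_relaxed))
    cat(sprintf("  knee_f = %.4g, t_relaxed = %.6g\n", x$knee_f, x$t_relaxed))
  invisible(x)
}

# TRUE when some candidate of the remaining-fraction curve rises credibly
# above the no-enrichment baseline F(0) = 1/2: the excess must exceed z
# binomial standard errors (sd <= 0.5/sqrt(k), with k the pooled number of
# blocks still above the candidate). With target and control statistically
# exchangeable the curve fluctuates around 1/2 at every scale and this test
# stays negative; any real enrichment drives F to ~1 while tens of blocks
# remain, which passes easily.
curve_has_enrichment <- function(curve, z = 4) {
  p_t <- curve$frac_target_remaining
  p_c <- curve$frac_control_remaining
  ok <- (p_t + p_c) > 0 & curve$n_remaining > 0
  f <- p_t[ok] / (p_t[ok] + p_c[ok])
  any(f - 0.5 > z * 0.5 / sqrt(curve$n_remaining[ok]))
}

#' Select the relaxed threshold from a curve's knee
#'
#' The relaxed threshold sits in F-space halfway between the curve maximum
#' and its negatively inflected "knee": the candidate with negative discrete
#' second difference (`F[i+1] - 2 F[i] + F[i-1] < 0`) and `F < f_max` whose F
#' value k is nearest below the maximum. The relaxed level is
#' `f_max - (f_max - k)/2`, and the threshold is the t at which F first
#' reaches that level, located by linear interpolation between the flanking
#' candidates. With no qualifying knee (or fewer than 3 candidates) the
#' relaxed threshold falls back to the stringent one.
#'
#' @param curve a `threshold_curve` from [compute_f_curve()].
#' @return the curve, with `knee_f` and `t_relaxed` filled in
#'   (`t_relaxed <= t_stringent` always holds).
#' @examples
#' cv <- list(candidates = 0:4, f_values = c(0.2, 0.6, 0.8, 0.9, 0.95),
#'            f_max = 0.95, t_stringent = 4, knee_f = NA, t_relaxed = NA)
#' class(cv) <- "threshold_curve"
#' select_relaxed(cv)$t_relaxed # 3.5
#' @export
select_relaxed <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  f <- curve$f_values
  tt <- curve$candidates
  k_n <- length(f)
  curve$t_relaxed <- curve$t_stringent
  if (k_n < 3L) {
    message("fewer than 3 threshold candidates; relaxed threshold falls ",
            "back to stringent")
    return(curve)
  }
  interior <- 2L:(k_n - 1L)
  d2 <- f[interior + 1L] - 2 * f[interior] + f[interior - 1L]
  ok <- d2 < 0 & f[interior] < curve$f_max
  if (!any(ok)) return(curve)
  cand_i <- interior[ok]
  knee_i <- cand_i[which.max(f[cand_i])]
  curve$knee_f <- f[knee_i]
  f_rel <- curve$f_max - (curve$f_max - curve$knee_f) / 2
  i <- which(f >= f_rel)[1L]
  t_rel <- if (i == 1L) tt[1L] else
    tt[i - 1L] + (tt[i] - tt[i - 1L]) * (f_rel - f[i - 1L]) / (f[i] - f[i - 1L])
  curve$t_relaxed <- min(t_rel, curve$t_stringent)
  curve
}

#' Control-free global threshold at a target quantile
#'
#' Without a control dataset, a threshold is set so that (about) the top `q`
#' fraction of target blocks by total signal exceed it: the top
#' `k = ceiling(q * m)` blocks are retained and the threshold is the
#' (k+1)-th largest total (0 when k >= m). A quantile is used rather than a
#' raw signal value because raw totals are sequencing-depth dependent.
#'
#' @param target_totals numeric vector of target block totals.
#' @param q fraction of blocks to retain, in (0, 1).
#' @return the threshold value (blocks with `total > threshold` are kept).
#' @examples
#' global_threshold(1:10, 0.2) # 8: blocks {9, 10} exceed it
#' @export
global_threshold <- function(target_totals, q) {
  if (!length(target_totals)) stop("target dataset has no signal blocks")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("global threshold fraction q must lie in (0, 1)")
  s <- sort(as.numeric(target_totals), decreasing = TRUE)
  m <- length(s)
  k <- ceiling(q * m)
  if (k >= m) 0 else s[k + 1L]
}

#' Empirical false discovery rate at a threshold
#'
#' The fraction of control signal blocks among all blocks remaining above the
#' threshold:
#' `#\{control > t\} / (#\{target > t\} + #\{control > t\})`, and 0 when no
#' block at all exceeds t.
#'
#' @param target_totals target block totals.
#' @param scaled_control_totals control block totals, already scaled when
#'   normalization is in use.
#' @param t threshold (>= 0).
#' @return list with `value`, `n_target_above`, `n_control_above`.
#' @examples
#' empirical_fdr(c(50, 60), c(10, 12), 12)$value # 0
#' @export
empirical_fdr <- function(target_totals, scaled_control_totals, t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  n_t <- sum(target_totals > t)
  n_c <- sum(scaled_control_totals > t)
  list(value = if (n_t + n_c > 0L) n_c / (n_t + n_c) else 0,
       n_target_above = n_t,
       n_control_above = n_c)
}
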