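test_that("F curve reproduces the worked micro-instances", {
  cv <- compute_f_curve(c(10, 10, 50, 60), c(10, 12))
  expect_equal(cv$candidates, c(0, 10, 12, 50)) # t = 60 excluded (nothing left)
  expect_equal(cv$f_values, c(0.5, 0.5, 1, 1))
  expect_equal(cv$f_max, 1)
  expect_equal(cv$t_stringent, 12)
  expect_equal(cv$frac_target_remaining[1], 1)
  expect_equal(cv$frac_control_remaining[1], 1)

  # control dominating every target total: best F is at t = 0
  cv2 <- compute_f_curve(5, 10)
  expect_equal(cv2$f_max, 0.5)
  expect_equal(cv2$t_stringent, 0)

  # identical datasets: F = 0.5 everywhere, smallest maximizer wins
  cv3 <- compute_f_curve(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(cv3$f_values == 0.5))
  expect_equal(cv3$t_stringent, 0)
})

test_that("F curve input contracts", {
  expect_error(compute_f_curve(numeric(), c(1, 2)), "no signal blocks")
  expect_error(compute_f_curve(c(1, 2), numeric()), "global_threshold")
})

test_that("remaining-block fractions are monotone and F stays in [0, 1]", {
  set.seed(11)
  for (i in 1:20) {
    rt <- rgamma(50, 2, 0.1)
    st <- rgamma(40, 2, 0.1)
    cv <- compute_f_curve(rt, st)
    expect_true(all(diff(cv$frac_target_remaining) <= 0))
    expect_true(all(diff(cv$frac_control_remaining) <= 0))
    expect_true(all(cv$f_values >= 0 & cv$f_values <= 1))
    expect_true(all(cv$candidates >= 0 & cv$candidates <= cv$t_max))
    expect_true(cv$t_stringent %in% cv$candidates)
  }
})

test_that("stringent selection matches exhaustive enumeration", {
  set.seed(23)
  for (i in 1:60) {
    rt <- sample(1:30, sample(1:50, 1), replace = TRUE)
    st <- sample(1:30, sample(1:50, 1), replace = TRUE)
    cv <- compute_f_curve(rt, st)
    want <- brute_f_best(rt, st)
    expect_identical(cv$f_max, want$f_max)
    expect_identical(cv$t_stringent, want$t_stringent)
  }
})

test_that("printed-equation variant is available and bounded", {
  cv <- compute_f_curve(c(10, 10, 50, 60), c(10, 12), variant = "printed")
  # t = 0 removes nothing: excluded (0/0); at t = 10, two of the three
  # removed blocks are target blocks
  expect_equal(cv$candidates[1], 10)
  expect_equal(cv$f_values[1], 2 / 3)
  expect_true(all(cv$f_values >= 0 & cv$f_values <= 1))
})

test_that("relaxed selection finds the knee and interpolates in F-space", {
  cv <- structure(list(candidates = as.numeric(0:4),
                       f_values = c(0.2, 0.6, 0.8, 0.9, 0.95),
                       f_max = 0.95, t_stringent = 4,
                       knee_f = NA_real_, t_relaxed = NA_real_),
                  class = "threshold_curve")
  out <- select_relaxed(cv)
  expect_equal(out$knee_f, 0.9)
  expect_equal(out$t_relaxed, 3.5) # F_relaxed = 0.925 between t = 3 and 4

  # negative inflection only at the maximum itself: fall back to stringent
  cv2 <- compute_f_curve(c(10, 10, 50, 60), c(10, 12))
  out2 <- select_relaxed(cv2)
  expect_true(is.na(out2$knee_f))
  expect_equal(out2$t_relaxed, out2$t_stringent)

  # flat curve: no knee
  cv3 <- compute_f_curve(c(1, 2, 3), c(1, 2, 3))
  expect_equal(select_relaxed(cv3)$t_relaxed, cv3$t_stringent)

  # fewer than 3 candidates: fallback with a notice
  cv4 <- compute_f_curve(5, 10)
  expect_message(out4 <- select_relaxed(cv4), "fewer than 3")
  expect_equal(out4$t_relaxed, out4$t_stringent)
})

test_that("relaxed threshold never exceeds stringent on random instances", {
  set.seed(31)
  for (i in 1:30) {
    rt <- rgamma(60, 2, 0.05)
    st <- rgamma(60, 1, 0.05)
    cv <- select_relaxed(compute_f_curve(rt, st))
    expect_lte(cv$t_relaxed, cv$t_stringent)
    expect_gte(sum(rt > cv$t_relaxed), sum(rt > cv$t_stringent))
  }
})

test_that("normalization locates density peaks and scales linearly", {
  nr <- normalize_control(rep(20, 1000), rep(10, 1000))
  expect_equal(nr$target_mode, 20)
  expect_equal(nr$control_mode, 10)
  expect_equal(nr$scaling_factor, 2)

  set.seed(5)
  x <- rgamma(500, 4, 0.02)
  expect_equal(normalize_control(x, x)$scaling_factor, 1)
  # KDE mode scales linearly with its sample
  for (c_scale in c(0.25, 0.5, 2, 3.7)) {
    nr <- normalize_control(x, c_scale * x)
    expect_equal(nr$scaling_factor, 1 / c_scale, tolerance = 1e-8)
  }
  expect_error(normalize_control(numeric(), x), "both datasets")
  expect_error(normalize_control(x, numeric()), "both datasets")
})

test_that("global threshold retains the ceiling-adjusted top fraction", {
  expect_equal(global_threshold(1:10, 0.2), 8)
  expect_equal(sum(1:10 > global_threshold(1:10, 0.2)), 2L)
  # q below 1/m keeps only the single largest block
  expect_equal(sum(1:10 > global_threshold(1:10, 0.05)), 1L)
  expect_error(global_threshold(1:10, 0), "\\(0, 1\\)")
  expect_error(global_threshold(1:10, 1), "\\(0, 1\\)")
  # degenerate all-equal totals: nothing strictly exceeds
  expect_equal(sum(rep(3, 5) > global_threshold(rep(3, 5), 0.2)), 0L)
})

test_that("empirical FDR counts control blocks among survivors", {
  fdr <- empirical_fdr(c(50, 60), c(10, 12), 12)
  expect_equal(fdr$value, 0)
  expect_equal(fdr$n_target_above, 2L)

  expect_equal(empirical_fdr(c(1, 2, 3), c(1, 2, 3), 0)$value, 0.5)
  fdr3 <- empirical_fdr(5, c(10, 20), 7)
  expect_equal(fdr3$value, 1)
  expect_equal(fdr3$n_control_above, 2L)
  # nothing above threshold: defined as 0
  expect_equal(empirical_fdr(c(1, 2), c(1, 2), 99)$value, 0)
})

test_that("iid null totals leave almost no target blocks above threshold", {
  # under exchangeability the curve never rises credibly above F(0) = 0.5,
  # so stringent selection falls back to the control-maximum threshold
  set.seed(77)
  frac <- replicate(20, {
    rt <- rgamma(200, 2, 0.1)
    st <- rgamma(200, 2, 0.1)
    cv <- compute_f_curve(rt, st)
    t_str <- if (sparsepeaks:::curve_has_enrichment(cv)) cv$t_stringent
             else max(st)
    mean(rt > t_str)
  })
  expect_true(all(frac <= 0.05))
})

test_that("enrichment safeguard separates real enrichment from null noise", {
  set.seed(78)
  # clear enrichment: 25 strong blocks over exchangeable background
  rt <- c(rgamma(300, 2, 0.1), rgamma(25, 2, 0.1) + 500)
  st <- rgamma(300, 2, 0.1)
  expect_true(sparsepeaks:::curve_has_enrichment(compute_f_curve(rt, st)))
  # exchangeable null: rarely (never, at these seeds) credible
  ok <- replicate(20, sparsepeaks:::curve_has_enrichment(
    compute_f_curve(rgamma(300, 2, 0.1), rgamma(300, 2, 0.1))))
  expect_true(!any(ok))
})
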