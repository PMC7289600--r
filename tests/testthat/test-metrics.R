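test_that("normalization anchors the stimulus frame at exactly 1", {
  tr <- fret_trace(0:2, c(2, 2, 3), stim_index = 2)
  expect_identical(normalize_trace(tr)$ratio, c(1, 1, 1.5))
  flat <- fret_trace(0:4, rep(2.7, 5), stim_index = 3)
  expect_identical(normalize_trace(flat)$ratio, rep(1, 5))
  # idempotence
  tr2 <- normalize_trace(tr)
  expect_identical(normalize_trace(tr2)$ratio, tr2$ratio)
  expect_error(normalize_trace(fret_trace(0:2, c(1, 1, 1), 1), stim_index = 0))
})

test_that("baseline averaging over k pre-stimulus frames is available", {
  tr <- fret_trace(0:4, c(1.8, 2.2, 2.0, 3.0, 4.0), stim_index = 3)
  n1 <- normalize_trace(tr)                       # R0 = 2.0
  nk <- normalize_trace(tr, baseline_frames = 3)  # R0 = mean(1.8, 2.2, 2.0)
  expect_equal(attr(n1, "r0_raw"), 2.0)
  expect_equal(attr(nk, "r0_raw"), 2.0)
  expect_equal(nk$ratio[4], 1.5)
})

test_that("maximum response statistics follow the post-stimulus definitions", {
  tr <- fret_trace(0:3 * 0.5, c(1.0, 1.2, 1.5, 1.3), stim_index = 1)
  mr <- max_response(tr)
  expect_equal(mr$max_over_baseline, 0.5)
  expect_equal(mr$max_dr_over_rmin, (1.5 - 1.2) / 1.2)
  expect_equal(mr$t_max_min, 1.0)
  # flat post-stimulus trace: both zero
  fl <- max_response(fret_trace(0:3, rep(1, 4), stim_index = 1))
  expect_equal(fl$max_over_baseline, 0)
  expect_equal(fl$max_dr_over_rmin, 0)
  # ties resolve to the earliest frame
  tie <- fret_trace(0:4, c(1, 1.2, 1.5, 1.1, 1.5), stim_index = 1)
  expect_equal(max_response(tie)$t_max_min, 2)
  expect_error(max_response(fret_trace(0:2, c(1, 1, 1), stim_index = 2)),
               "2 frames")
})

test_that("SAM40 hits its analytic anchors", {
  t <- seq(0, 45, by = 0.5)
  # plateau: R40 == Rmax -> 1
  plateau <- fret_trace(t, c(1, rep(1.745, length(t) - 1)), stim_index = 1)
  expect_equal(sam40(plateau), 1, tolerance = 1e-15)
  # full return: R40 == R0 -> 0 (peak at 5 min, back to baseline by 40)
  ret <- approx(c(0, 5, 40, 45), c(1, 1.7, 1, 1), xout = t)$y
  full_ret <- fret_trace(t, ret, stim_index = 1)
  expect_equal(sam40(full_ret), 0, tolerance = 1e-12)
  # direct evaluation: R0 = 1, Rmax = 1.745, R40 = 1.370
  vals <- approx(c(0, 10, 40, 45), c(1, 1.745, 1.370, 1.370), xout = t)$y
  tr <- fret_trace(t, vals, stim_index = 1)
  expect_equal(sam40(tr), 0.370 / 0.745, tolerance = 1e-12)
})

test_that("SAM40 is affine-invariant and reports undershoot unclamped", {
  set.seed(42)
  for (i in 1:25) {
    t <- seq(0, 45, by = 0.5)
    r <- exp(cumsum(rnorm(length(t), 0, 0.03)))
    tr <- fret_trace(t, r, stim_index = 3)
    s <- sam40(tr)
    if (!is.finite(s)) next
    a <- runif(1, 0.5, 3)
    b <- runif(1, -0.2, 0.5)
    tr2 <- fret_trace(t, a * r + b, stim_index = 3)
    expect_equal(sam40(tr2), s, tolerance = 1e-12)
  }
  # undershoot below baseline is reported negative
  t <- seq(0, 45, by = 0.5)
  under <- c(1, 1.5, seq(1.5, 0.6, length.out = length(t) - 2))
  expect_lt(sam40(fret_trace(t, under, stim_index = 1)), 0)
})

test_that("degenerate non-responders yield NaN with a warning, short traces error", {
  t <- seq(0, 45, by = 0.5)
  flat2 <- fret_trace(t, rep(1, length(t)), stim_index = 1)
  expect_warning(s <- sam40(flat2), "egenerate")
  expect_true(is.nan(s))
  short <- fret_trace(seq(0, 20, 0.5), rep(1, 41), stim_index = 1)
  expect_error(sam40(short), "min required")
})

test_that("time to half-max interpolates the first crossing", {
  # linear rise 1 -> 2 over 0..20 min post-stimulus: t1/2 = 10
  t <- seq(0, 20, by = 0.5)
  tr <- fret_trace(t, 1 + t / 20, stim_index = 1)
  expect_equal(time_to_half_max(tr), 10, tolerance = 1e-12)
  # saturating closed form: t1/2 = ln 2 / k for a long enough trace
  p <- kinetic_params("sustained", amplitude = 0.6, k_act = 0.0693,
                      k_dec = 0, noise_sd = 0)
  tr2 <- simulate_trace(p, n_frames = 246, stim_index = 6)
  expect_lt(abs(time_to_half_max(normalize_trace(tr2)) - log(2) / 0.0693), 0.5)
  # immediate step: within one frame interval
  step <- fret_trace(0:10 * 0.5, c(1, rep(2, 10)), stim_index = 1)
  expect_lte(time_to_half_max(step), 0.5)
  expect_error(time_to_half_max(fret_trace(0:5, rep(1, 6), stim_index = 1)),
               "Rmax")
})

test_that("slope change recovers piecewise-linear slopes exactly", {
  tr <- piecewise_trace(0.01, -0.02)
  sc <- slope_change(tr, addition_time_min = 10, window_min = 5)
  expect_equal(sc$slope_before, 0.01, tolerance = 1e-12)
  expect_equal(sc$slope_after, -0.02, tolerance = 1e-12)
  expect_equal(sc$delta, -0.03, tolerance = 1e-12)
  flat <- piecewise_trace(0, 0)
  expect_equal(slope_change(flat, 10)$delta, 0, tolerance = 1e-12)
  expect_error(slope_change(tr, 10, window_min = 1), "3 frames")
})

test_that("noisy slopes are recovered within their OLS standard errors", {
  set.seed(19)
  hits <- 0L
  n_fit <- 0L
  for (i in 1:100) {
    tr <- piecewise_trace(0.01, -0.02, t_break = 30, t_end = 60,
                          noise_sd = 0.01)
    sc <- slope_change(tr, 30, window_min = 25)
    hits <- hits + (abs(sc$slope_before - 0.01) <= 3 * sc$se_before) +
      (abs(sc$slope_after + 0.02) <= 3 * sc$se_after)
    n_fit <- n_fit + 2L
  }
  expect_gte(hits / n_fit, 0.99)
})

test_that("vectorised metrics agree with the brute-force oracle on random traces", {
  fx <- random_trace_set(n_per_model = 25, seed = 2)
  m <- trace_metrics(fx$traces, stim_index = fx$stim_index)
  split_tr <- split(fx$traces, fx$traces$cell_id)
  for (i in seq_len(nrow(m))) {
    df <- split_tr[[m$cell_id[i]]]
    o <- oracle_metrics(df$time_min, df$ratio / df$ratio[fx$stim_index],
                        fx$stim_index)
    expect_equal(m$sam40[i], o$sam40, tolerance = 1e-12)
    expect_equal(m$max_over_baseline[i], o$max_over_baseline, tolerance = 1e-12)
    expect_equal(m$max_dr_over_rmin[i], o$max_dr_over_rmin, tolerance = 1e-12)
    expect_equal(m$t_half_min[i], o$t_half_min, tolerance = 1e-12)
    expect_equal(m$t_max_min[i], o$t_max_min, tolerance = 1e-12)
  }
})
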