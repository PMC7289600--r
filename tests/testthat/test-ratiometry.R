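make_uniform_stack <- function(acceptor, donor, h = 8, w = 8, n_t = 3) {
  fret_stack(list(acceptor = array(acceptor, c(h, w, n_t)),
                  donor = array(donor, c(h, w, n_t))),
             pixel_size_um = 0.5, frame_interval_s = 30)
}

test_that("background subtraction removes the per-frame cell-free mean and floors at 0", {
  h <- 6; w <- 6
  donor <- array(500, c(h, w, 2))
  donor[2, 2, 1] <- 800; donor[2, 2, 2] <- 800   # one bright pixel
  bg <- matrix(FALSE, h, w); bg[5:6, ] <- TRUE
  donor[5:6, , 1] <- 100; donor[5:6, , 2] <- 110
  st <- fret_stack(list(donor = donor), 0.5, 30)
  out <- background_subtract(st, bg)
  expect_equal(out$channels$donor[2, 2, 1], 700)
  expect_equal(out$channels$donor[2, 2, 2], 690)
  # uniform frame equal to its background mean becomes all zeros
  st2 <- make_uniform_stack(500, 500)
  bg2 <- matrix(TRUE, 8, 8)
  expect_true(all(background_subtract(st2, bg2)$channels$donor == 0))
  # values below the background floor at 0
  donor[2, 2, 1] <- 50
  st3 <- fret_stack(list(donor = donor), 0.5, 30)
  expect_equal(background_subtract(st3, bg)$channels$donor[2, 2, 1], 0)
})

test_that("background subtraction is idempotent on a zero-mean background", {
  h <- 6; w <- 6
  bg <- matrix(FALSE, h, w); bg[1:2, ] <- TRUE
  arr <- array(150, c(h, w, 3)); arr[1:2, , ] <- 0
  st <- fret_stack(list(donor = arr), 0.5, 30)
  once <- background_subtract(st, bg)
  expect_equal(background_subtract(once, bg)$channels$donor,
               once$channels$donor)
})

test_that("ratio traces follow the region-mean quotient and its invariances", {
  st <- make_uniform_stack(150, 100)
  roi <- matrix(FALSE, 8, 8); roi[3:5, 3:5] <- TRUE
  tr <- extract_trace(st, roi, stim_index = 1)
  expect_equal(tr$ratio, rep(1.5, 3))
  # identical channels give 1
  st_id <- make_uniform_stack(100, 100)
  expect_equal(extract_trace(st_id, roi)$ratio, rep(1, 3))
  # invariant under common positive scaling of both channels
  st_scaled <- make_uniform_stack(150 * 7.3, 100 * 7.3)
  expect_equal(extract_trace(st_scaled, roi)$ratio, tr$ratio)
  # non-positive denominator rejected unless explicitly allowed
  st0 <- make_uniform_stack(150, 0)
  expect_error(extract_trace(st0, roi), "not positive")
  expect_warning(tr0 <- extract_trace(st0, roi, allow_nan = TRUE), "NaN")
  expect_true(all(is.nan(tr0$ratio)))
})

test_that("noiseless synthetic stacks reproduce programmed ramps near machine precision", {
  t <- seq(0, 9.5, by = 0.5)
  ramp <- seq(1.0, 1.8, length.out = length(t))
  traces <- tibble::tibble(cell_id = "cell_001", time_min = t, ratio = ramp)
  layout <- tibble::tibble(cell_id = "cell_001", x = 20, y = 20, r = 7)
  sim <- simulate_ratiometric_stack(traces, layout, dim = c(48, 48))
  ext <- extract_traces(sim$stack, sim$rois, stim_index = 1)
  expect_lt(max(abs(ext$traces$ratio - ramp) / ramp), 1e-9)
  # constant programmed ratio 1.0 stays flat at 1.0 after normalization
  traces1 <- tibble::tibble(cell_id = "cell_001", time_min = t, ratio = 1)
  sim1 <- simulate_ratiometric_stack(traces1, layout, dim = c(48, 48))
  ext1 <- extract_traces(sim1$stack, sim1$rois, stim_index = 1)
  norm <- normalize_trace(fret_trace(t, ext1$traces$ratio, 1))
  expect_equal(norm$ratio, rep(1, length(t)), tolerance = 1e-12)
})

test_that("noisy extraction stays within the propagated 3-sigma ratio band", {
  set.seed(8)
  t <- seq(0, 49.5, by = 0.5)
  ramp <- seq(1.0, 1.8, length.out = length(t))
  traces <- tibble::tibble(cell_id = "cell_001", time_min = t, ratio = ramp)
  layout <- tibble::tibble(cell_id = "cell_001", x = 20, y = 20, r = 8)
  sim <- simulate_ratiometric_stack(traces, layout, dim = c(56, 56),
                                    read_noise_sd = 20, seed = 99)
  ext <- extract_traces(sim$stack, sim$rois, stim_index = 1)
  n_px <- sum(sim$rois$cells$cell_001)
  n_bg <- sum(sim$rois$background)
  sds <- ratio_noise_sd(ramp, 1000, 20, n_px, n_bg)
  frac <- mean(abs(ext$traces$ratio - ramp) <= 3 * sds)
  expect_gte(frac, 0.99)
})

test_that("stack generator rejects invalid geometry", {
  t <- 0:4
  traces <- tibble::tibble(cell_id = rep(c("a", "b"), each = 5),
                           time_min = rep(t, 2), ratio = 1)
  layout <- tibble::tibble(cell_id = c("a", "b"), x = c(20, 28), y = 20,
                           r = c(6, 6))
  expect_error(simulate_ratiometric_stack(traces, layout, dim = c(48, 48)),
               "overlap")
  layout2 <- tibble::tibble(cell_id = c("a", "b"), x = c(3, 40), y = 20,
                            r = c(6, 6))
  expect_error(simulate_ratiometric_stack(traces, layout2, dim = c(48, 48)),
               "inside")
})

test_that("stacks round-trip through TIFF byte-losslessly for integer counts", {
  arr <- array(sample(0:65535, 16 * 16 * 4, replace = TRUE), c(16, 16, 4))
  st <- fret_stack(list(acceptor = arr, donor = arr + 0), 0.5, 30)
  dir <- withr::local_tempdir()
  paths <- write_stack(st, dir)
  back <- read_stack(paths, pixel_size_um = 0.5, frame_interval_s = 30)
  expect_identical(back$channels$acceptor, st$channels$acceptor + 0)
  # mismatched frame counts across channels are rejected
  st_b <- fret_stack(list(donor = arr[, , 1:3]), 0.5, 30)
  write_stack(st_b, dir, prefix = "short")
  expect_error(read_stack(c(acceptor = paths[["acceptor"]],
                            donor = file.path(dir, "short_donor.tif")),
                          0.5, 30), "disagree")
})
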