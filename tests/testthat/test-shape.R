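test_that("equivalent-ellipse axes recover programmed ellipse geometry", {
  # filled circle: ratio 1 within discretization error
  circ <- rotated_ellipse_mask(80, 80, 40, 40, 30, 30, 0)
  ax <- equivalent_axes(circ, pixel_size_um = 0.5)
  expect_lt(abs(ax$axis_ratio - 1), 0.02)
  # ellipse semi-axes 40/24 px at 0.25 um/px: major 20 um, minor 12 um
  ell <- rotated_ellipse_mask(100, 120, 60, 50, 40, 24, 0)
  ax2 <- equivalent_axes(ell, pixel_size_um = 0.25)
  expect_lt(abs(ax2$major_um - 20) / 20, 0.02)
  expect_lt(abs(ax2$minor_um - 12) / 12, 0.02)
  expect_lt(abs(ax2$axis_ratio - 0.6), 0.02 * 0.6 * 2)
  # tiny or fragmented masks are rejected
  tiny <- matrix(FALSE, 10, 10); tiny[5, 4:6] <- TRUE
  expect_error(equivalent_axes(tiny), "20 pixels")
  two <- matrix(FALSE, 40, 40)
  two[5:14, 5:14] <- TRUE; two[25:34, 25:34] <- TRUE
  expect_error(equivalent_axes(two), "one connected component")
  expect_error(equivalent_axes(matrix(FALSE, 5, 5)), "empty")
})

test_that("axis ratio is rotation-invariant within discretization error", {
  for (ang in c(0, 30, 45, 60, 90)) {
    m <- rotated_ellipse_mask(140, 140, 70, 70, 40, 24, ang)
    ax <- equivalent_axes(m, pixel_size_um = 0.5)
    expect_lt(abs(ax$axis_ratio - 0.6) / 0.6, 0.02)
  }
})

test_that("the major-axis line follows the equivalent-ellipse orientation", {
  m <- rotated_ellipse_mask(120, 120, 60, 60, 40, 20, 0)
  ln <- major_axis_line(m)
  expect_lt(abs(ln$y1 - ln$y0), 1e-6)  # horizontal
  m45 <- rotated_ellipse_mask(160, 160, 80, 80, 40, 20, 45)
  ln45 <- major_axis_line(m45)
  ang <- atan2(ln45$y1 - ln45$y0, ln45$x1 - ln45$x0) * 180 / pi
  expect_lt(abs(abs(ang) - 45), 1)
  # circle: orientation undefined, deterministic x-axis fallback with warning
  circ <- rotated_ellipse_mask(80, 80, 40, 40, 25, 25, 0)
  expect_warning(lnc <- major_axis_line(circ), "circular")
  expect_lt(abs(lnc$y1 - lnc$y0), 1e-6)
})

test_that("kymograph dimensions and static-profile behaviour are correct", {
  movie <- array(0, c(50, 100, 20))
  movie[20:30, 10:90, ] <- 1
  line <- tibble::tibble(x0 = 11, y0 = 25, x1 = 90, y1 = 25)
  k <- build_kymograph(movie, line, pixel_size_um = 0.5, frame_interval_s = 30)
  expect_identical(dim(k), c(80L, 20L))  # line length 79 px -> 80 samples
  expect_true(all(k == k[, 1]))  # static movie: all columns identical
  bad <- tibble::tibble(x0 = -5, y0 = 25, x1 = 90, y1 = 25)
  expect_error(build_kymograph(movie, bad, 0.5, 30), "bounds")
})

test_that("programmed protrusions are recovered exactly from the kymograph", {
  spec <- tibble::tibble(onset_min = 2, end_min = 22, extension_um = 6,
                         side = "right")
  mv <- simulate_protrusion_movie(c(40, 30), spec, n_frames = 60)
  expect_identical(mv$events$extension_px, 12L)
  expect_identical(mv$events$n_frames, 40L)
  line <- major_axis_line(mv$movie[, , 1] > 0.5, extend_frac = 0.5)
  k <- build_kymograph(mv$movie, line, mv$pixel_size_um, mv$frame_interval_s)
  ev <- detect_protrusions(k, stim_index = 4)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$max_extension_um, 6)
  expect_equal(ev$persistence_min, 20)
  expect_equal(ev$side, "right")
  expect_equal(ev$onset_min, 2)
})

test_that("static movies yield no events and sub-threshold protrusions are discarded", {
  mv0 <- simulate_protrusion_movie(c(30, 20), NULL, n_frames = 30)
  expect_true(all(mv0$movie[, , 1] == mv0$movie[, , 30]))
  line <- major_axis_line(mv0$movie[, , 1] > 0.5, extend_frac = 0.4)
  k <- build_kymograph(mv0$movie, line, mv0$pixel_size_um, 30)
  expect_identical(nrow(detect_protrusions(k, stim_index = 3)), 0L)
  # a 0.4 um excursion is below the 1 um default minimum
  tiny <- tibble::tibble(onset_min = 2, end_min = 10, extension_um = 0.4,
                         side = "right")
  mvt <- simulate_protrusion_movie(c(30, 20), tiny, n_frames = 30,
                                   pixel_size_um = 0.2)
  linet <- major_axis_line(mvt$movie[, , 1] > 0.5, extend_frac = 0.4)
  kt <- build_kymograph(mvt$movie, linet, 0.2, 30)
  expect_identical(nrow(detect_protrusions(kt, stim_index = 3)), 0L)
})

test_that("two opposite-side protrusions give exactly two events", {
  spec <- tibble::tibble(onset_min = c(2, 5), end_min = c(12, 20),
                         extension_um = c(4, 6), side = c("left", "right"))
  mv <- simulate_protrusion_movie(c(40, 30), spec, n_frames = 50)
  expect_identical(nrow(mv$events), 2L)
  line <- major_axis_line(mv$movie[, , 1] > 0.5, extend_frac = 0.5)
  k <- build_kymograph(mv$movie, line, mv$pixel_size_um, 30)
  ev <- detect_protrusions(k, stim_index = 4)
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$side, c("left", "right"))
  expect_equal(sort(ev$max_extension_um), c(4, 6))
})

test_that("protrusions that exit the field of view are rejected", {
  spec <- tibble::tibble(onset_min = 2, end_min = 10, extension_um = 50,
                         side = "right")
  expect_error(simulate_protrusion_movie(c(40, 30), spec, n_frames = 30,
                                         dim = c(71, 100)),
               "field of view")
  expect_error(simulate_protrusion_movie(c(20, 30), NULL), "a >= b")
})

test_that("population classification applies strict thresholds", {
  morph <- tibble::tibble(cell_id = sprintf("c%d", 1:4),
                          axis_ratio = c(0.9, 0.9, 0.5, 0.7))
  cl <- classify_population(morph)
  expect_equal(cl$frac_round, 0.5)
  expect_equal(cl$frac_elongated, 0.25)
  # every cell with one 6 um / 20 min event: both protrusion fractions 1
  ev <- tibble::tibble(cell_id = morph$cell_id, max_extension_um = 6,
                       persistence_min = 20)
  cl2 <- classify_population(morph, ev)
  expect_equal(cl2$frac_long_protrusion, 1)
  expect_equal(cl2$frac_long_persistent, 1)
  expect_error(classify_population(morph[0, ]), "Empty")
})
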