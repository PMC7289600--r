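test_that("a gross outlier among constants is flagged and pure constants are not", {
  x <- c(rep(0, 19), 100)
  expect_warning(mask <- rout_outliers(x), "IQR")  # MAD is 0 here
  expect_identical(which(mask), 20L)
  expect_identical(rout_outliers(rep(3.2, 10)), rep(FALSE, 10))
  expect_error(rout_outliers(c(1, 2, 3)), "at least 5")
  expect_error(rout_outliers(c(1, 2, 3, NA, 5, 6)), "finite")
})

test_that("planted 10-sigma points are flagged at Q = 1% and match the documented rule", {
  set.seed(4)
  x <- c(rnorm(100), rep(10, 5))
  mask <- rout_outliers(x, q = 0.01)
  expect_true(all(mask[101:105]))
  # independent brute-force evaluation of the documented variant
  z <- (x - median(x)) / (1.4826 * median(abs(x - median(x))))
  p <- 2 * pt(-abs(z), df = length(x) - 1)
  ord <- order(p)
  thresh <- 0.01 * seq_along(p) / length(p)
  k <- max(c(0, which(p[ord] <= thresh)))
  expected <- rep(FALSE, length(p))
  if (k > 0) expected[ord[seq_len(k)]] <- TRUE
  expect_identical(mask, expected)
})

test_that("outlier flags are invariant under affine transforms", {
  set.seed(9)
  x <- c(rnorm(50), 8, -7)
  base <- rout_outliers(x)
  for (a in c(0.01, -3, 250)) {
    expect_identical(rout_outliers(a * x + 17), base)
  }
})

test_that("pearson_r matches hand-computed product-moment values", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(1:5, rep(1, 5)), "zero-variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

make_metric_table <- function(n = 60, seed = 1, coupled = FALSE) {
  set.seed(seed)
  expr <- rnorm(n, 1000, 150)
  resp <- rnorm(n, 0.745, 0.1)
  if (coupled) {
    expr[1:6] <- 1000 + sample(c(-1, 1), 6, TRUE) * runif(6, 750, 900)
    resp[1:6] <- pmax(0.745 * (1 + (expr[1:6] - 1000) / 750), 0.02)
  }
  tibble::tibble(cell_id = sprintf("c%03d", seq_len(n)), condition = "x",
                 max_over_baseline = resp, sam40 = rnorm(n, 0.4, 0.08),
                 start_ratio = rnorm(n, 1.2, 0.05), mean_fluorescence = expr,
                 is_artifact = c(rep(coupled, 6), rep(FALSE, n - 6)))
}

test_that("expression filter leaves an uncoupled population untouched", {
  tab <- make_metric_table(n = 100, seed = 2)
  q <- filter_expression_artifacts(tab)
  expect_identical(nrow(q$removed), 0L)
  expect_identical(nrow(q$retained), 100L)
  expect_false(q$report$unfiltered)
})

test_that("expression filter removes coupled cells until |r| < 0.5", {
  tab <- make_metric_table(n = 60, seed = 3, coupled = TRUE)
  r0 <- pearson_r(tab$max_over_baseline, tab$mean_fluorescence)
  expect_gt(abs(r0), 0.5)
  q <- filter_expression_artifacts(tab)
  expect_lt(q$report$final_max_abs_r, 0.5)
  expect_false(q$report$unfiltered)
  # removed cells are flagged with the pair that triggered each removal
  expect_true(all(c("metric", "covariate", "abs_r") %in% names(tidy(q))))
  expect_gte(mean(q$removed$cell_id %in% tab$cell_id[tab$is_artifact]), 0.5)
  # condition-local: duplicating the table under a second condition label
  # yields the same removals per condition
  tab2 <- dplyr::mutate(tab, condition = "y",
                        cell_id = paste0("y", cell_id))
  q2 <- filter_expression_artifacts(dplyr::bind_rows(tab, tab2))
  expect_identical(sort(sub("^y", "", q2$removed$cell_id[q2$removed$condition == "y"])),
                   sort(q$removed$cell_id))
})

test_that("a perfectly collinear pair stops at the floor with an unfiltered flag", {
  n <- 12
  tab <- tibble::tibble(cell_id = sprintf("c%02d", 1:n), condition = "x",
                        max_over_baseline = seq(0.1, 1.2, length.out = n),
                        sam40 = rnorm(n, 0.4, 0.05),
                        start_ratio = rnorm(n, 1.2, 0.05),
                        mean_fluorescence = 1000 * seq(0.1, 1.2, length.out = n))
  q <- filter_expression_artifacts(tab, min_cells = 5)
  expect_identical(nrow(q$retained), 5L)
  expect_true(q$report$unfiltered)
  expect_identical(q$report$n_removed, 7L)
  expect_error(filter_expression_artifacts(tab[1:3, ]), "at least 5")
})

test_that("filter terminates within n - min_cells iterations by construction", {
  tab <- make_metric_table(n = 30, seed = 5, coupled = TRUE)
  q <- filter_expression_artifacts(tab, min_cells = 5)
  expect_lte(nrow(q$removed), 25)
  expect_identical(max(q$removed$iteration), nrow(q$removed))
})
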