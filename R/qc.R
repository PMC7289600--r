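#' FDR-controlled robust outlier flagging
#'
#' A single-sample variant of FDR-based robust outlier detection for
#' one-dimensional metric samples: values are centred on the median and
#' scaled by 1.4826 * MAD, two-sided tail probabilities are taken from a
#' t-distribution with n - 1 degrees of freedom, and a Benjamini-Hochberg
#' step-up at rate `q` marks the outliers. This follows the intent of the
#' regression-based ROUT procedure (robust fit + FDR) but is defined for a
#' plain sample rather than a nonlinear regression, and is fully
#' documented and testable.
#'
#' @param x Numeric vector, `n >= 5`, all finite.
#' @param q False-discovery rate (default 0.01, i.e. Q = 1%).
#' @return Logical vector marking outliers. Flags are invariant under any
#'   affine transform of `x`. A sample of identical values yields no flags;
#'   a zero MAD with non-identical values falls back to an IQR-based scale
#'   with a warning.
#' @examples
#' rout_outliers(c(rnorm(20), 100))
#' @export
rout_outliers <- function(x, q = 0.01) {
  if (length(x) < 5L) abort("Need at least 5 values.")
  if (!all(is.finite(x))) abort("All values must be finite.")
  if (all(x == x[1])) return(rep(FALSE, length(x)))
  z <- robust_z(x)
  p <- 2 * pt(-abs(z), df = length(x) - 1)
  p.adjust(p, method = "BH") <= q
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with nonzero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Pearson correlation is undefined for a zero-variance input.")
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Iterative Pearson filter for biosensor expression artifacts
#'
#' Cells whose extremely high or low biosensor expression drives their
#' apparent response are removed condition by condition: while any
#' |Pearson r| between a response metric and an expression covariate
#' (starting ratio or starting fluorescence) reaches `r_threshold` and more
#' than `min_cells` cells remain, the cell with the most extreme robust
#' z-score on the covariate of the worst (largest |r|) pair is removed and
#' all correlations recomputed. The procedure removes one cell per
#' iteration, so it terminates in at most `n - min_cells` steps; if the
#' threshold cannot be reached before hitting the floor, the condition is
#' retained at `min_cells` cells and flagged unfiltered.
#'
#' @param table Per-cell metric tibble with a `cell_id`, a `condition`
#'   column (created as `"all"` when absent), the response metrics and the
#'   covariates; no missing values allowed in those columns.
#' @param response_metrics Character vector of response metric columns.
#' @param covariates Character vector of expression covariate columns.
#' @param r_threshold Absolute correlation below which a condition is
#'   considered clean (default 0.5).
#' @param min_cells Minimum retained cells per condition (default 5).
#' @return A list of class `fret_qc_filter`: `retained` (the filtered
#'   table), `removed` (tibble of removed cells with the iteration, worst
#'   pair and |r| that triggered each removal), and `report` (one row per
#'   condition: cells in/out, final worst |r|, `unfiltered` flag).
#' @export
filter_expression_artifacts <- function(table,
                                        response_metrics = c("max_over_baseline", "sam40"),
                                        covariates = c("start_ratio", "mean_fluorescence"),
                                        r_threshold = 0.5, min_cells = 5L) {
  if (!"cell_id" %in% names(table)) abort("`table` needs a `cell_id` column.")
  if (!"condition" %in% names(table)) table$condition <- "all"
  cols <- c(response_metrics, covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    abort(sprintf("Missing columns: %s.", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(table[cols])) {
    abort("Missing values in metric/covariate columns; drop degenerate cells first.")
  }
  pairs <- tidyr::expand_grid(metric = response_metrics, covariate = covariates)

  worst_pair <- function(df) {
    rs <- purrr::pmap_dbl(pairs, function(metric, covariate) {
      m <- df[[metric]]; cv <- df[[covariate]]
      if (var(m) == 0 || var(cv) == 0) 0 else pearson_r(m, cv)
    })
    k <- which.max(abs(rs))
    list(metric = pairs$metric[k], covariate = pairs$covariate[k], r = rs[k])
  }

  removed <- list(); report <- list()
  retained <- list()
  for (cond in unique(table$condition)) {
    df <- table[table$condition == cond, ]
    n0 <- nrow(df)
    if (n0 < min_cells) {
      abort(sprintf("Condition '%s' has %d cells; at least %d required.",
                    cond, n0, min_cells))
    }
    iter <- 0L
    repeat {
      wp <- worst_pair(df)
      if (abs(wp$r) < r_threshold || nrow(df) <= min_cells) break
      iter <- iter + 1L
      z <- robust_z(df[[wp$covariate]], warn_fallback = FALSE)
      drop_i <- which.max(abs(z))
      removed[[length(removed) + 1L]] <- tibble::tibble(
        cell_id = df$cell_id[drop_i], condition = cond, iteration = iter,
        metric = wp$metric, covariate = wp$covariate, abs_r = abs(wp$r))
      df <- df[-drop_i, ]
    }
    final <- worst_pair(df)
    report[[length(report) + 1L]] <- tibble::tibble(
      condition = cond, n_start = n0, n_retained = nrow(df),
      n_removed = n0 - nrow(df), final_max_abs_r = abs(final$r),
      unfiltered = abs(final$r) >= r_threshold)
    retained[[length(retained) + 1L]] <- df
  }
  structure(list(retained = purrr::list_rbind(retained),
                 removed = if (length(removed)) purrr::list_rbind(removed) else
                   tibble::tibble(cell_id = character(), condition = character(),
                                  iteration = integer(), metric = character(),
                                  covariate = character(), abs_r = numeric()),
                 report = purrr::list_rbind(report)),
            class = "fret_qc_filter")
}

#' @export
print.fret_qc_filter <- function(x, ...) {
  cat(sprintf("<fret_qc_filter> %d condition(s), %d cell(s) removed\n",
              nrow(x$report), nrow(x$removed)))
  print(x$report)
  invisible(x)
}

#' @describeIn filter_expression_artifacts Per-removal detail as a tibble.
#' @param x A `fret_qc_filter` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fret_qc_filter <- function(x, ...) x$removed

#' @describeIn filter_expression_artifacts Per-condition summary as a
#'   tibble.
#' @exportS3Method generics::glance
glance.fret_qc_filter <- function(x, ...) x$report
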