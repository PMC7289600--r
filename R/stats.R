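#' Per-condition summaries of a metric
#'
#' Mean, standard error of the mean (sd/sqrt(n)) and the t-based 95%
#' confidence interval, per condition.
#'
#' @param table Per-cell tibble with a `condition` column and the metric.
#' @param metric Name of the metric column (string).
#' @param conf_level Confidence level for the interval.
#' @return A tibble: `condition`, `n_cells`, `mean`, `sd`, `sem`,
#'   `ci_low`, `ci_high`.
#' @examples
#' df <- tibble::tibble(condition = "a", sam40 = c(1, 2, 3))
#' summarize_population(df, "sam40")  # sem = 0.5774
#' @export
summarize_population <- function(table, metric, conf_level = 0.95) {
  if (!metric %in% names(table)) abort(sprintf("No column `%s`.", metric))
  if (!"condition" %in% names(table)) table$condition <- "all"
  out <- table |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean = mean(.data[[metric]]),
                     sd = sd(.data[[metric]]),
                     .groups = "drop")
  if (any(out$n_cells < 2L)) {
    abort("Every condition needs at least 2 cells for a summary.")
  }
  out |>
    dplyr::mutate(
      sem = .data$sd / sqrt(.data$n_cells),
      ci_low = .data$mean - qt((1 + conf_level) / 2, .data$n_cells - 1) * .data$sem,
      ci_high = .data$mean + qt((1 + conf_level) / 2, .data$n_cells - 1) * .data$sem)
}

#' Two-condition comparison by unpaired t-test
#'
#' Runs both the pooled-variance and Welch unpaired t-tests and selects
#' between them: by default Welch's correction is applied when an F-test of
#' the two variances rejects equality at the 0.05 level, and the pooled
#' test otherwise. Two constant, equal groups return t = 0, p = 1 by
#' convention.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param welch `"auto"` (F-test decides), `"always"` or `"never"`.
#' @param var_alpha Significance level of the variance F-test in auto mode.
#' @return A list of class `fret_comparison` with the chosen test, both
#'   component tests and the variance test. `tidy()` returns all tests as
#'   rows; `glance()` the chosen one.
#' @export
compare_two <- function(x, y, welch = c("auto", "always", "never"),
                        var_alpha = 0.05) {
  welch <- match.arg(welch)
  if (length(x) < 2L || length(y) < 2L) abort("Each group needs n >= 2.")
  degenerate <- var(x) == 0 && var(y) == 0
  if (degenerate && mean(x) == mean(y)) {
    res <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                p.value = 1, method = "degenerate (identical constant groups)")
    out <- list(chosen = res, welch = res, pooled = res, var_test = NULL,
                used = "degenerate")
    class(out) <- "fret_comparison"
    return(out)
  }
  if (degenerate) {
    # equal-variance (zero) groups with different means: pooled t is infinite
    res <- list(statistic = sign(mean(x) - mean(y)) * Inf,
                parameter = length(x) + length(y) - 2, p.value = 0,
                method = "degenerate (distinct constant groups)")
    out <- list(chosen = res, welch = res, pooled = res, var_test = NULL,
                used = "degenerate")
    class(out) <- "fret_comparison"
    return(out)
  }
  w <- t.test(x, y, var.equal = FALSE)
  p <- t.test(x, y, var.equal = TRUE)
  vt <- if (var(x) > 0 && var(y) > 0) var.test(x, y) else NULL
  used <- switch(welch,
                 always = "welch",
                 never = "pooled",
                 auto = if (!is.null(vt) && vt$p.value < var_alpha) "welch" else "pooled")
  out <- list(chosen = if (used == "welch") w else p,
              welch = w, pooled = p, var_test = vt, used = used)
  class(out) <- "fret_comparison"
  out
}

#' @export
print.fret_comparison <- function(x, ...) {
  cat(sprintf("<fret_comparison> %s t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$used, x$chosen$statistic, x$chosen$parameter,
              x$chosen$p.value))
  invisible(x)
}

comparison_row <- function(ht, label) {
  tibble::tibble(test = label,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' @describeIn compare_two All component tests, one row each.
#' @param x A `fret_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fret_comparison <- function(x, ...) {
  out <- dplyr::bind_rows(comparison_row(x$welch, "welch"),
                          comparison_row(x$pooled, "pooled"))
  if (!is.null(x$var_test)) {
    out <- dplyr::bind_rows(out, comparison_row(x$var_test, "variance_F"))
  }
  out$chosen <- out$test == x$used |
    (x$used == "degenerate" & out$test == "welch")
  out
}

#' @describeIn compare_two The selected test as one row.
#' @exportS3Method generics::glance
glance.fret_comparison <- function(x, ...) {
  dplyr::mutate(comparison_row(x$chosen, x$used), method = x$chosen$method)
}

#' Multi-condition comparison: one-way ANOVA with Tukey HSD
#'
#' Ordinary one-way ANOVA across conditions followed by Tukey honest
#' significant difference pairwise comparisons with adjusted p-values.
#' Groups with zero within-group variance but distinct means are handled
#' without error (F reported as infinite, p as 0).
#'
#' @param values Numeric vector of per-cell metric values, or a data frame
#'   with the metric and group columns.
#' @param groups Group labels (vector), or the group column name when
#'   `values` is a data frame.
#' @param metric Metric column name when `values` is a data frame.
#' @return A list of class `fret_anova`: `anova` (one-row tibble with F,
#'   dfs and p) and `pairwise` (Tukey-adjusted pairwise tibble).
#' @export
compare_many <- function(values, groups, metric = NULL) {
  if (is.data.frame(values)) {
    df <- tibble::tibble(value = values[[metric]],
                         group = factor(values[[groups]]))
  } else {
    df <- tibble::tibble(value = values, group = factor(groups))
  }
  counts <- table(df$group)
  if (length(counts) < 2L) abort("Need at least 2 groups.")
  if (any(counts < 2L)) abort("Every group needs at least 2 values.")
  within_ss <- sum(tapply(df$value, df$group, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    grand <- mean(df$value)
    between_ss <- sum(tapply(df$value, df$group,
                             function(v) length(v) * (mean(v) - grand)^2))
    f <- if (between_ss > 0) Inf else 0
    p <- if (between_ss > 0) 0 else 1
    lev <- levels(df$group)
    pw <- tidyr::expand_grid(a = lev, b = lev) |>
      dplyr::filter(.data$a < .data$b) |>
      dplyr::mutate(contrast = paste(.data$b, .data$a, sep = "-"),
                    diff = purrr::map2_dbl(.data$b, .data$a, function(b, a) {
                      mean(df$value[df$group == b]) - mean(df$value[df$group == a])
                    }),
                    p_adj = ifelse(.data$diff != 0, 0, 1)) |>
      dplyr::select("contrast", "diff", "p_adj")
    out <- list(anova = tibble::tibble(df_between = length(lev) - 1,
                                       df_within = nrow(df) - length(lev),
                                       statistic = f, p_value = p),
                pairwise = pw)
    class(out) <- "fret_anova"
    return(out)
  }
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  out <- list(
    anova = tibble::tibble(df_between = s[1, "Df"], df_within = s[2, "Df"],
                           statistic = s[1, "F value"],
                           p_value = s[1, "Pr(>F)"]),
    pairwise = tibble::tibble(contrast = rownames(tk),
                              diff = tk[, "diff"],
                              ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                              p_adj = tk[, "p adj"]))
  class(out) <- "fret_anova"
  out
}

#' @export
print.fret_anova <- function(x, ...) {
  cat(sprintf("<fret_anova> F(%g, %g) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$statistic,
              x$anova$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @describeIn compare_many Pairwise comparisons as a tibble.
#' @param x A `fret_anova`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fret_anova <- function(x, ...) x$pairwise

#' @describeIn compare_many The ANOVA table as one row.
#' @exportS3Method generics::glance
glance.fret_anova <- function(x, ...) x$anova
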