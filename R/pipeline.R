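cfg_get <- function(config, path, default = NULL, required = FALSE) {
  node <- config
  for (key in path) {
    if (!is.list(node) || is.null(node[[key]])) {
      if (required) {
        abort(sprintf("Config schema error: missing required field `%s`.",
                      paste(path, collapse = "$")))
      }
      return(default)
    }
    node <- node[[key]]
  }
  node
}

#' Run the full single-cell analysis pipeline
#'
#' Chains simulation (or trace loading), per-cell metric computation, QC
#' (degenerate-cell flagging, FDR-controlled outlier flagging, the
#' iterative expression-artifact filter, manual exclusions), condition
#' summaries and condition comparisons, writing every intermediate as CSV
#' plus a config echo and a log. Outputs are a pure function of the config
#' (including its seed): rerunning with the same config yields
#' byte-identical CSVs.
#'
#' @param config A config list, or the path of a YAML file holding one.
#'   Required fields: `seed`; `input$type` (`"simulate"` or
#'   `"traces_csv"`) with its sub-config. See the package vignette for the
#'   schema.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the `traces`, `metrics` (QC-annotated),
#'   `retained`, `summary` and `comparisons` tibbles and the per-condition
#'   `qc_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  seed <- cfg_get(config, "seed", required = TRUE)
  out_dir <- out_dir %||% cfg_get(config, "out_dir", required = TRUE)
  input_type <- cfg_get(config, c("input", "type"), required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (input_type == "simulate") {
    sim <- cfg_get(config, c("input", "simulate"), required = TRUE)
    conds <- cfg_get(sim, "conditions", required = TRUE)
    stim_index <- cfg_get(sim, "stim_index", 6L)
    frame_interval_s <- cfg_get(sim, "frame_interval_s", 30)
    n_frames <- cfg_get(sim, "n_frames", 96L)
    pops <- withr::with_seed(seed, lapply(conds, function(cc) {
      simulate_population(
        n_cells = cfg_get(cc, "n_cells", required = TRUE),
        model = cfg_get(cc, "model", required = TRUE),
        params = cfg_get(cc, "params", list()),
        artifact_fraction = cfg_get(cc, "artifact_fraction", 0),
        n_frames = n_frames, frame_interval_s = frame_interval_s,
        stim_index = stim_index,
        condition = cfg_get(cc, "name", required = TRUE))
    }))
    # prefix ids with the condition so cells are unique across conditions
    traces <- purrr::list_rbind(purrr::map(pops, function(p) {
      dplyr::mutate(p$traces,
                    cell_id = paste(.data$condition, .data$cell_id, sep = "_"))
    }))
    covariates_tbl <- purrr::list_rbind(purrr::map(pops, function(p) {
      dplyr::mutate(p$cells,
                    cell_id = paste(.data$condition, .data$cell_id, sep = "_"))
    })) |>
      dplyr::select("cell_id", "start_ratio", "mean_fluorescence")
    covariate_cols <- c("start_ratio", "mean_fluorescence")
  } else if (input_type == "traces_csv") {
    tc <- cfg_get(config, c("input", "traces_csv"), required = TRUE)
    path <- cfg_get(tc, "path", required = TRUE)
    if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
    stim_index <- cfg_get(tc, "stim_index", required = TRUE)
    traces <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("cell_id", "time_min", "ratio") %in% names(traces))) {
      abort("Traces CSV needs columns cell_id, time_min, ratio.")
    }
    if (!"condition" %in% names(traces)) traces$condition <- "all"
    cells_path <- cfg_get(tc, "cells_path")
    if (!is.null(cells_path)) {
      covariates_tbl <- readr::read_csv(cells_path, show_col_types = FALSE)
      covariate_cols <- intersect(c("start_ratio", "mean_fluorescence"),
                                  names(covariates_tbl))
    } else {
      covariates_tbl <- traces |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(start_ratio = .data$ratio[stim_index],
                         .groups = "drop")
      covariate_cols <- "start_ratio"
    }
  } else {
    abort(sprintf("Config schema error: unknown `input$type` '%s'.", input_type))
  }

  t_eval_min <- cfg_get(config, c("metrics", "t_eval_min"), 40)
  baseline_frames <- cfg_get(config, c("metrics", "baseline_frames"), 1L)
  metrics <- trace_metrics(traces, stim_index = stim_index,
                           t_eval_min = t_eval_min,
                           baseline_frames = baseline_frames) |>
    dplyr::left_join(covariates_tbl, by = "cell_id")

  manual <- cfg_get(config, c("qc", "manual_exclude"), character())
  rout_q <- cfg_get(config, c("qc", "rout_q"), 0.01)
  rout_metric <- cfg_get(config, c("qc", "rout_metric"), "max_over_baseline")
  metrics <- metrics |>
    dplyr::mutate(qc_manual = .data$cell_id %in% manual) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(qc_rout = !.data$degenerate &
                    rout_outliers_safe(.data[[rout_metric]], .data$degenerate,
                                       q = rout_q)) |>
    dplyr::ungroup()

  clean <- metrics |>
    dplyr::filter(!.data$degenerate, !.data$qc_manual, !.data$qc_rout)
  run_expr_filter <- isTRUE(cfg_get(config, c("qc", "expression_filter"), TRUE))
  if (run_expr_filter) {
    qc <- filter_expression_artifacts(
      clean,
      response_metrics = cfg_get(config, c("qc", "response_metrics"),
                                 c("max_over_baseline", "sam40")),
      covariates = cfg_get(config, c("qc", "covariates"), covariate_cols),
      r_threshold = cfg_get(config, c("qc", "r_threshold"), 0.5),
      min_cells = cfg_get(config, c("qc", "min_cells"), 5L))
    retained <- qc$retained
    qc_removed <- qc$removed
    qc_report <- qc$report
  } else {
    retained <- clean
    qc_removed <- tibble::tibble(cell_id = character(), condition = character(),
                                 iteration = integer(), metric = character(),
                                 covariate = character(), abs_r = numeric())
    qc_report <- tibble::tibble(condition = unique(clean$condition),
                                n_start = NA_integer_, n_retained = NA_integer_,
                                n_removed = 0L, final_max_abs_r = NA_real_,
                                unfiltered = NA)
  }
  metrics$qc_expression_artifact <- metrics$cell_id %in% qc_removed$cell_id
  metrics$retained <- metrics$cell_id %in% retained$cell_id

  stat_metrics <- cfg_get(config, c("stats", "metrics"),
                          c("sam40", "max_over_baseline"))
  summary_tbl <- purrr::list_rbind(lapply(stat_metrics, function(m) {
    dplyr::mutate(summarize_population(retained, m), metric = m,
                  .before = 1)
  }))
  n_cond <- length(unique(retained$condition))
  comparisons <- if (n_cond >= 2) {
    purrr::list_rbind(lapply(stat_metrics, function(m) {
      cm <- compare_many(retained, "condition", m)
      dplyr::mutate(dplyr::cross_join(glance(cm), tidy(cm)),
                    metric = m, .before = 1)
    }))
  } else {
    tibble::tibble()
  }

  wcsv <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  wcsv(traces, "traces.csv")
  wcsv(metrics, "cell_metrics.csv")
  wcsv(qc_removed, "qc_removals.csv")
  wcsv(qc_report, "qc_report.csv")
  wcsv(summary_tbl, "summary.csv")
  if (nrow(comparisons)) wcsv(comparisons, "comparisons.csv")
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  log_lines <- c(
    sprintf("fretquant %s on R %s.%s", utils::packageVersion("fretquant"),
            R.version$major, R.version$minor),
    sprintf("config hash: %s", rlang::hash(config)),
    sprintf("seed: %s", seed),
    sprintf("cells analysed: %d; retained after QC: %d", nrow(metrics),
            nrow(retained)),
    sprintf("excluded: %d degenerate, %d outlier, %d expression artifact, %d manual",
            sum(metrics$degenerate), sum(metrics$qc_rout),
            sum(metrics$qc_expression_artifact), sum(metrics$qc_manual)),
    paste("removed cells:", paste(qc_removed$cell_id, collapse = " ")))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(traces = traces, metrics = metrics, retained = retained,
                 summary = summary_tbl, comparisons = comparisons,
                 qc_report = qc_report))
}

rout_outliers_safe <- function(x, degenerate, q) {
  out <- rep(FALSE, length(x))
  ok <- !degenerate & is.finite(x)
  if (sum(ok) >= 5L) out[ok] <- rout_outliers(x[ok], q = q)
  out
}
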