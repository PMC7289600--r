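#' Normalize a ratio trace to its pre-stimulus baseline
#'
#' Divides the ratio at every time point by the basal value R0, so that the
#' normalized trace equals exactly 1 at the baseline frame. R0 is the single
#' frame immediately preceding drug addition by default; for noisy data
#' `baseline_frames = k` averages the last k pre-stimulus frames instead.
#'
#' @param trace A trace tibble with `time_min` and `ratio` columns.
#' @param stim_index Last pre-stimulus frame; defaults to the trace
#'   attribute.
#' @param baseline_frames Number of trailing pre-stimulus frames averaged to
#'   form R0 (default 1: the single frame at `stim_index`).
#' @return A `fret_trace` tibble of normalized values (`ratio` is now R/R0)
#'   with attribute `r0_raw` holding the raw baseline ratio.
#' @examples
#' tr <- fret_trace(time_min = 0:2, ratio = c(2, 2, 3), stim_index = 2)
#' normalize_trace(tr)$ratio  # 1.0 1.0 1.5
#' @export
normalize_trace <- function(trace, stim_index = NULL, baseline_frames = 1L) {
  trace_columns(trace)
  si <- resolve_stim_index(trace, stim_index)
  if (baseline_frames < 1L || baseline_frames > si) {
    abort("`baseline_frames` must be between 1 and `stim_index`.")
  }
  r0 <- mean(trace$ratio[(si - baseline_frames + 1L):si])
  if (!is.finite(r0) || r0 <= 0) abort("Baseline ratio R0 must be > 0.")
  out <- trace
  out$ratio <- trace$ratio / r0
  if (baseline_frames == 1L) out$ratio[si] <- 1  # exact, no float residue
  if ("ratio_true" %in% names(out)) out$ratio_true <- NULL
  attr(out, "stim_index") <- si
  attr(out, "r0_raw") <- r0
  if (!inherits(out, "fret_trace")) class(out) <- c("fret_trace", class(out))
  out
}

post_stim_window <- function(trace, si) {
  idx <- (si + 1L):nrow(trace)
  if (nrow(trace) - si < 2L) {
    abort("Need at least 2 frames after the stimulus.")
  }
  idx
}

#' Maximum response of a trace
#'
#' Rmax and Rmin are the maximum and minimum ratio recorded strictly after
#' stimulation. Two magnitudes are reported: `max_dr_over_rmin` =
#' (Rmax - Rmin)/Rmin, and `max_over_baseline` = (Rmax - R0)/R0, the percent
#' increase over the pre-stimulus value (on the fractional scale). Ties in
#' Rmax resolve to the earliest frame for the peak time.
#'
#' @inheritParams normalize_trace
#' @return A one-row tibble: `r_max`, `r_min`, `max_over_baseline`,
#'   `max_dr_over_rmin`, `t_max_min` (peak time, minutes after stimulus).
#' @examples
#' tr <- fret_trace(0:3 * 0.5, c(1, 1.2, 1.5, 1.3), stim_index = 1)
#' max_response(tr)
#' @export
max_response <- function(trace, stim_index = NULL) {
  trace_columns(trace)
  si <- resolve_stim_index(trace, stim_index)
  idx <- post_stim_window(trace, si)
  r0 <- trace$ratio[si]
  post <- trace$ratio[idx]
  r_max <- max(post)
  r_min <- min(post)
  i_max <- idx[which.max(post)]  # which.max -> earliest tie
  tibble::tibble(
    r_max = r_max,
    r_min = r_min,
    max_over_baseline = (r_max - r0) / r0,
    max_dr_over_rmin = (r_max - r_min) / r_min,
    t_max_min = trace$time_min[i_max] - trace$time_min[si]
  )
}

#' Sustained activity metric at 40 minutes (SAM40)
#'
#' Quantifies how sustained a single-cell response is:
#' `(R40 - R0) / (Rmax - R0)`, where R0 is the ratio at the last pre-stimulus
#' frame, Rmax the maximum ratio recorded after stimulation, and R40 the
#' ratio `t_eval_min` minutes (default 40) after the stimulus, linearly
#' interpolated between the bracketing frames when no frame falls exactly
#' there. A value of 1 means fully sustained activity; 0 means a full return
#' to baseline; values below 0 indicate an undershoot (reported, never
#' clamped). The statistic is invariant under any affine rescaling of the
#' trace, so raw and normalized traces give identical values.
#'
#' @inheritParams normalize_trace
#' @param t_eval_min Evaluation time, minutes after the stimulus.
#' @return A single number, or `NaN` (with a warning) for a degenerate
#'   non-responder whose Rmax equals R0.
#' @examples
#' tr <- fret_trace(seq(0, 45, 0.5), c(1, rep(1.745, 90)), stim_index = 1)
#' sam40(tr)  # plateau at Rmax: 1
#' @export
sam40 <- function(trace, stim_index = NULL, t_eval_min = 40) {
  trace_columns(trace)
  si <- resolve_stim_index(trace, stim_index)
  idx <- post_stim_window(trace, si)
  t_stim <- trace$time_min[si]
  t_eval <- t_stim + t_eval_min
  if (t_eval > trace$time_min[nrow(trace)]) {
    abort(sprintf("Trace ends %.2f min after the stimulus; %.0f min required.",
                  trace$time_min[nrow(trace)] - t_stim, t_eval_min))
  }
  r0 <- trace$ratio[si]
  r_max <- max(trace$ratio[idx])
  if (r_max == r0) {
    warn("Degenerate non-responder (Rmax == R0); SAM40 is undefined.")
    return(NaN)
  }
  r40 <- interp_at(trace$time_min, trace$ratio, t_eval)
  (r40 - r0) / (r_max - r0)
}

#' Time to half-maximal response
#'
#' The first time after the stimulus at which the trace crosses
#' R0 + 0.5 * (Rmax - R0), linearly interpolated between the bracketing
#' frames and reported in minutes relative to the stimulus frame. Used as a
#' proxy for the activation kinetics of a response.
#'
#' @inheritParams normalize_trace
#' @return Minutes from stimulus to the half-maximal crossing.
#' @examples
#' tr <- fret_trace(seq(0, 20, 0.5), c(1, seq(1, 2, length.out = 40)),
#'                  stim_index = 1)
#' time_to_half_max(tr)
#' @export
time_to_half_max <- function(trace, stim_index = NULL) {
  trace_columns(trace)
  si <- resolve_stim_index(trace, stim_index)
  idx <- post_stim_window(trace, si)
  r0 <- trace$ratio[si]
  r_max <- max(trace$ratio[idx])
  if (r_max <= r0) abort("Rmax must exceed R0 for a half-max time.")
  level <- r0 + 0.5 * (r_max - r0)
  t_stim <- trace$time_min[si]
  prev_t <- t_stim
  prev_r <- r0
  for (i in idx) {
    r <- trace$ratio[i]
    if (r >= level) {
      tt <- if (r == prev_r) trace$time_min[i] else
        prev_t + (level - prev_r) / (r - prev_r) * (trace$time_min[i] - prev_t)
      return(tt - t_stim)
    }
    prev_t <- trace$time_min[i]
    prev_r <- r
  }
  abort("Trace never crosses the half-maximal level.")  # unreachable: Rmax >= level
}

#' Slope change around a drug addition
#'
#' Fits ordinary least-squares slopes to the trace in the windows
#' `[addition - window, addition)` and `(addition, addition + window]` and
#' reports their difference. An immediate change of slope after adding a
#' kinase inhibitor indicates the kinase was still actively phosphorylating
#' the biosensor at that time.
#'
#' @inheritParams normalize_trace
#' @param addition_time_min Time of the addition, minutes (same clock as
#'   `time_min`).
#' @param window_min Width of each fitting window, minutes.
#' @return A one-row tibble: `slope_before`, `slope_after` (ratio units per
#'   minute), `delta` (after minus before), and the OLS standard errors
#'   `se_before`, `se_after`.
#' @export
slope_change <- function(trace, addition_time_min, window_min = 5) {
  trace_columns(trace)
  t <- trace$time_min
  before <- t >= addition_time_min - window_min & t < addition_time_min
  after <- t > addition_time_min & t <= addition_time_min + window_min
  if (sum(before) < 3L || sum(after) < 3L) {
    abort("Need at least 3 frames in each window around the addition.")
  }
  fit <- function(sel) {
    m <- lm(ratio ~ time_min, data = trace[sel, ])
    s <- suppressWarnings(summary(m)$coefficients)  # exact fits are fine here
    c(slope = unname(coef(m)[2]), se = unname(s["time_min", "Std. Error"]))
  }
  b <- fit(before)
  a <- fit(after)
  tibble::tibble(slope_before = unname(b["slope"]),
                 slope_after = unname(a["slope"]),
                 delta = unname(a["slope"] - b["slope"]),
                 se_before = unname(b["se"]), se_after = unname(a["se"]))
}

#' Per-cell response metrics for a population of traces
#'
#' Normalizes each cell's trace to its baseline and computes the full metric
#' set: R0 (raw), Rmax, Rmin, R40 (normalized scale), SAM40,
#' (Rmax - Rmin)/Rmin, (Rmax - R0)/R0, time of peak and time to half-max.
#' Cells whose response is degenerate (Rmax equal to R0, so SAM40 is
#' undefined) are flagged rather than dropped.
#'
#' @param traces A long tibble with columns `cell_id`, `time_min`, `ratio`
#'   and optionally `condition`.
#' @param stim_index Last pre-stimulus frame (shared by all cells).
#' @param t_eval_min Evaluation time for the sustained activity metric.
#' @param baseline_frames Pre-stimulus frames averaged into R0.
#' @return A tibble with one row per cell: identifiers, `r0_raw`, `r_max`,
#'   `r_min`, `r40`, `sam40`, `max_over_baseline`, `max_dr_over_rmin`,
#'   `t_max_min`, `t_half_min`, and a logical `degenerate` QC flag.
#' @export
trace_metrics <- function(traces, stim_index, t_eval_min = 40,
                          baseline_frames = 1L) {
  if (!all(c("cell_id", "time_min", "ratio") %in% names(traces))) {
    abort("`traces` needs columns `cell_id`, `time_min`, `ratio`.")
  }
  has_cond <- "condition" %in% names(traces)
  traces |>
    dplyr::group_by(.data$cell_id,
                    !!!(if (has_cond) rlang::syms("condition") else NULL)) |>
    dplyr::group_modify(function(df, key) {
      tr <- fret_trace(df$time_min, df$ratio, stim_index = stim_index)
      norm <- normalize_trace(tr, baseline_frames = baseline_frames)
      mr <- max_response(norm)
      s40 <- withCallingHandlers(
        sam40(norm, t_eval_min = t_eval_min),
        warning = function(w) invokeRestart("muffleWarning")
      )
      degenerate <- !is.finite(s40)
      t_half <- if (mr$r_max > 1) time_to_half_max(norm) else NA_real_
      t_stim <- norm$time_min[stim_index]
      r40 <- interp_at(norm$time_min, norm$ratio, t_stim + t_eval_min)
      tibble::tibble(
        r0_raw = attr(norm, "r0_raw"), r_max = mr$r_max, r_min = mr$r_min,
        r40 = r40, sam40 = s40,
        max_over_baseline = mr$max_over_baseline,
        max_dr_over_rmin = mr$max_dr_over_rmin,
        t_max_min = mr$t_max_min, t_half_min = t_half,
        degenerate = degenerate
      )
    }) |>
    dplyr::ungroup()
}
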