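#' Construct a ratio trace
#'
#' A ratio trace is a tibble with one row per frame and columns `time_min`
#' (strictly increasing, minutes) and `ratio` (dimensionless, positive
#' acceptor/donor emission ratio). The index of the last pre-stimulus frame
#' and any later drug additions are carried as attributes so that downstream
#' metric functions pick them up automatically; every metric function also
#' accepts them as explicit arguments.
#'
#' @param time_min Numeric vector of frame times in minutes, strictly
#'   increasing.
#' @param ratio Numeric vector of ratio values, same length as `time_min`,
#'   all positive (zero is tolerated transiently after background flooring).
#' @param stim_index Integer index of the last frame acquired before the
#'   stimulus was added; the ratio at this frame is the baseline R0.
#' @param cell_id Optional cell identifier.
#' @param condition Optional condition label.
#' @param additions Optional tibble of later drug additions with columns
#'   `time_min` and `label` (e.g. an ERK inhibitor added after EGF).
#' @return A tibble of class `fret_trace` with columns `time_min` and `ratio`.
#' @examples
#' tr <- fret_trace(time_min = seq(0, 5, by = 0.5), ratio = rep(1.2, 11),
#'                  stim_index = 3)
#' stim_index(tr)
#' @export
fret_trace <- function(time_min, ratio, stim_index = 1L, cell_id = NULL,
                       condition = NULL, additions = NULL) {
  if (length(time_min) != length(ratio)) {
    abort("`time_min` and `ratio` must have the same length.")
  }
  if (any(diff(time_min) <= 0)) {
    abort("`time_min` must be strictly increasing.")
  }
  check_stim_index(stim_index, length(time_min))
  out <- tibble::tibble(time_min = as.numeric(time_min),
                        ratio = as.numeric(ratio))
  attr(out, "stim_index") <- as.integer(stim_index)
  attr(out, "cell_id") <- cell_id
  attr(out, "condition") <- condition
  attr(out, "additions") <- additions
  class(out) <- c("fret_trace", class(out))
  out
}

#' Stimulus frame index of a trace
#'
#' @param trace A trace tibble (see [fret_trace()]).
#' @return Integer index of the last pre-stimulus frame, or `NULL` when the
#'   object carries none.
#' @export
stim_index <- function(trace) attr(trace, "stim_index", exact = TRUE)

check_stim_index <- function(stim_index, n_frames) {
  if (is.null(stim_index) || length(stim_index) != 1L || is.na(stim_index) ||
      stim_index < 1L || stim_index > n_frames) {
    abort("`stim_index` must be a single frame index within the trace.")
  }
  invisible(as.integer(stim_index))
}

resolve_stim_index <- function(trace, stim_index) {
  si <- stim_index %||% stim_index(trace)
  if (is.null(si)) {
    abort("`stim_index` is required: pass it or use a trace created with `fret_trace()`.")
  }
  check_stim_index(si, nrow(trace))
}

trace_columns <- function(trace) {
  if (!all(c("time_min", "ratio") %in% names(trace))) {
    abort("A trace needs `time_min` and `ratio` columns.")
  }
  invisible(trace)
}

# Linear interpolation of the trace value at an arbitrary time.
interp_at <- function(time_min, ratio, t) {
  if (t < time_min[1] || t > time_min[length(time_min)]) {
    abort(sprintf("Time %.3g min lies outside the trace (%.3g..%.3g min).",
                  t, time_min[1], time_min[length(time_min)]))
  }
  approx(time_min, ratio, xout = t, method = "linear", ties = "ordered")$y
}

# Robust z-scores: centre = median, scale = 1.4826 * MAD, with an IQR-based
# fallback (IQR/1.349 estimates sigma for a normal sample) when the MAD
# collapses on a heavily tied sample.
robust_z <- function(x, warn_fallback = TRUE) {
  ctr <- median(x)
  scl <- mad(x, center = ctr)  # constant 1.4826 is stats::mad's default
  if (scl == 0) {
    if (all(x == x[1])) return(rep(0, length(x)))
    scl <- IQR(x) / 1.349
    if (scl == 0) scl <- sd(x)
    if (warn_fallback) {
      warn("MAD is zero with non-identical values; falling back to an IQR-based scale.")
    }
  }
  (x - ctr) / scl
}
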