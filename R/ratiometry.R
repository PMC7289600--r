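#' Mean intensity of a region over time
#'
#' @param stack A [fret_stack()].
#' @param roi Logical `H x W` mask.
#' @param channel Channel name.
#' @return Numeric vector (one mean per frame).
#' @export
roi_mean <- function(stack, roi, channel) {
  stopifnot(inherits(stack, "fret_stack"))
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("No channel named '%s'.", channel))
  }
  arr <- stack$channels[[channel]]
  if (!identical(dim(roi), dim(arr)[1:2])) {
    abort("Region mask dimensions must match the stack.")
  }
  if (sum(roi) == 0L) abort("Region is empty.")
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  colMeans(flat[as.vector(roi), , drop = FALSE])
}

#' Background-subtract a stack
#'
#' For every channel and frame, subtracts the mean intensity of the
#' cell-free background region in that frame from every pixel, flooring the
#' result at 0 (counts are physical). The per-frame mean absorbs slow lamp
#' drift.
#'
#' @param stack A [fret_stack()].
#' @param background Logical `H x W` mask of the cell-free region (or a
#'   [fret_rois()] whose `$background` is used).
#' @return A background-corrected [fret_stack()].
#' @export
background_subtract <- function(stack, background) {
  stopifnot(inherits(stack, "fret_stack"))
  if (inherits(background, "fret_rois")) background <- background$background
  corrected <- lapply(stack$channels, function(arr) {
    d <- dim(arr)
    flat <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
    bg <- colMeans(flat[as.vector(background), , drop = FALSE])
    out <- sweep(flat, 2L, bg, `-`)
    out[out < 0] <- 0
    array(out, dim = d)
  })
  fret_stack(corrected, stack$pixel_size_um, stack$frame_interval_s)
}

#' Extract a single-cell ratio trace from a background-corrected stack
#'
#' The per-frame ratio is the mean of the numerator channel over the cell
#' region divided by the mean of the denominator channel over the same
#' region (acceptor/donor, i.e. Y/C, for emission ratiometry; GFP/RFP for a
#' TIRF translocation assay). Apply [background_subtract()] first.
#'
#' @param stack A background-corrected [fret_stack()].
#' @param roi Logical `H x W` mask of the cell.
#' @param numerator,denominator Channel names.
#' @param stim_index Last pre-stimulus frame recorded on the trace.
#' @param cell_id,condition Optional labels.
#' @param allow_nan If `TRUE`, frames whose denominator mean is not positive
#'   yield `NaN` with a warning instead of an error.
#' @return A `fret_trace` tibble (`time_min`, `ratio`).
#' @export
extract_trace <- function(stack, roi, numerator = "acceptor",
                          denominator = "donor", stim_index = 1L,
                          cell_id = NULL, condition = NULL,
                          allow_nan = FALSE) {
  num <- roi_mean(stack, roi, numerator)
  den <- roi_mean(stack, roi, denominator)
  bad <- den <= 0
  if (any(bad)) {
    if (!allow_nan) {
      abort(sprintf(
        "Denominator region mean is not positive at %d frame(s) (first: %d); set `allow_nan = TRUE` to keep them as NaN.",
        sum(bad), which(bad)[1]))
    }
    warn(sprintf("Denominator mean not positive at %d frame(s); ratio set to NaN.",
                 sum(bad)))
  }
  r <- ifelse(bad, NaN, num / den)
  fret_trace(stack_times_min(stack), r, stim_index = stim_index,
             cell_id = cell_id, condition = condition)
}

#' Extract traces for every cell in a region set
#'
#' Background-subtracts the stack using the set's cell-free region, then
#' extracts one ratio trace per cell region. The donor mean at the stimulus
#' frame is recorded per cell as `mean_fluorescence` (a biosensor expression
#' proxy used by the QC filters), along with the raw starting ratio.
#'
#' @param stack A raw [fret_stack()].
#' @param rois A [fret_rois()] set.
#' @inheritParams extract_trace
#' @return A list with `traces` (long tibble: `cell_id`, `time_min`,
#'   `ratio`) and `cells` (tibble: `cell_id`, `start_ratio`,
#'   `mean_fluorescence`).
#' @export
extract_traces <- function(stack, rois, numerator = "acceptor",
                           denominator = "donor", stim_index = 1L,
                           allow_nan = FALSE) {
  stopifnot(inherits(rois, "fret_rois"))
  corrected <- background_subtract(stack, rois$background)
  per_cell <- purrr::imap(rois$cells, function(mask, id) {
    tr <- extract_trace(corrected, mask, numerator, denominator,
                        stim_index = stim_index, cell_id = id,
                        allow_nan = allow_nan)
    don <- roi_mean(corrected, mask, denominator)
    list(trace = tibble::tibble(cell_id = id, time_min = tr$time_min,
                                ratio = tr$ratio),
         cells = tibble::tibble(cell_id = id,
                                start_ratio = tr$ratio[stim_index],
                                mean_fluorescence = don[stim_index]))
  })
  list(traces = purrr::list_rbind(purrr::map(per_cell, "trace")),
       cells = purrr::list_rbind(purrr::map(per_cell, "cells")))
}
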