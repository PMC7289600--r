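#' Equivalent-ellipse axes of a cell mask
#'
#' Fits the equivalent ellipse of the second central moments of the mask's
#' foreground: the ellipse with the same area-normalized second moments as
#' the pixel set. Axis lengths are four times the square roots of the
#' covariance eigenvalues (exact for an ideal solid ellipse), converted to
#' micrometres. The minor:major ratio is the standard roundness measure
#' (1 = circular).
#'
#' @param mask Logical (or 0/1) `H x W` matrix with a single connected
#'   foreground component of at least 20 pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A one-row tibble: `major_um`, `minor_um`, `axis_ratio`
#'   (minor/major), `orientation_deg` (major-axis angle from the +x image
#'   axis, degrees in (-90, 90]), `centroid_x`, `centroid_y` (pixels),
#'   `area_px`.
#' @export
equivalent_axes <- function(mask, pixel_size_um = 1) {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a matrix.")
  area <- sum(mask)
  if (area == 0L) abort("Mask is empty.")
  if (area < 20L) abort("Foreground must contain at least 20 pixels.")
  labels <- EBImage::bwlabel(mask * 1)
  if (max(labels) != 1L) {
    abort(sprintf("Mask must contain exactly one connected component (found %d); isolate cells first.",
                  max(labels)))
  }
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  mx <- mean(xs); my <- mean(ys)
  cxx <- mean((xs - mx)^2); cyy <- mean((ys - my)^2)
  cxy <- mean((xs - mx) * (ys - my))
  tr2 <- (cxx + cyy) / 2
  det_rt <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- tr2 + det_rt; l2 <- max(tr2 - det_rt, 0)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  major_px <- 4 * sqrt(l1); minor_px <- 4 * sqrt(l2)
  tibble::tibble(major_um = major_px * pixel_size_um,
                 minor_um = minor_px * pixel_size_um,
                 axis_ratio = minor_px / major_px,
                 orientation_deg = theta * 180 / pi,
                 centroid_x = mx, centroid_y = my,
                 area_px = area)
}

#' Line along the major axis of a cell mask
#'
#' Returns the endpoints of a line through the mask centroid along the
#' equivalent-ellipse orientation, extended by a margin beyond the baseline
#' boundary on each side so that later protrusions stay on the line, and
#' clipped to the image. For a near-circular mask the orientation is
#' undefined; the line then falls back deterministically to the image
#' x-axis with a warning.
#'
#' @inheritParams equivalent_axes
#' @param extend_frac Fractional extension of each half-axis beyond the
#'   baseline cell boundary (default 0.25).
#' @param circular_tol Relative eigenvalue gap below which the mask is
#'   treated as circular.
#' @return A one-row tibble with endpoints `x0`, `y0`, `x1`, `y1` in pixel
#'   coordinates (1-based, x = column).
#' @export
major_axis_line <- function(mask, extend_frac = 0.25, circular_tol = 1e-3) {
  ax <- equivalent_axes(mask, pixel_size_um = 1)
  h <- nrow(if (is.logical(mask)) mask else mask > 0.5); w <- ncol(mask)
  theta <- ax$orientation_deg * pi / 180
  if ((ax$major_um - ax$minor_um) / ax$major_um < circular_tol) {
    warn("Mask is circular within tolerance; major-axis orientation undefined, using the image x-axis.")
    theta <- 0
  }
  half <- ax$major_um / 2 * (1 + extend_frac)
  dx <- cos(theta); dy <- sin(theta)
  # shrink symmetrically until both endpoints are inside the image
  tmax <- half
  for (s in c(-1, 1)) {
    x <- ax$centroid_x + s * half * dx; y <- ax$centroid_y + s * half * dy
    if (dx != 0) {
      tmax <- min(tmax, abs((ifelse(s * dx > 0, w, 1) - ax$centroid_x) / dx))
    }
    if (dy != 0) {
      tmax <- min(tmax, abs((ifelse(s * dy > 0, h, 1) - ax$centroid_y) / dy))
    }
  }
  half <- min(half, tmax)
  tibble::tibble(x0 = ax$centroid_x - half * dx, y0 = ax$centroid_y - half * dy,
                 x1 = ax$centroid_x + half * dx, y1 = ax$centroid_y + half * dy)
}

#' Build a kymograph along a line
#'
#' Samples the image profile along a fixed line at every frame
#' (nearest-pixel sampling, 1-pixel line width). Row i of the result is the
#' i-th position along the line; column t is frame t, so the kymograph maps
#' distance (rows, in pixels of known size) against time (columns, one
#' frame interval per pixel).
#'
#' @param movie A `H x W x T` array (e.g. a mask movie), or a
#'   [fret_stack()] plus `channel`.
#' @param line One-row tibble or list with `x0`, `y0`, `x1`, `y1` (pixels).
#' @param pixel_size_um,frame_interval_s Calibration; taken from the stack
#'   when `movie` is a [fret_stack()].
#' @param channel Channel name when `movie` is a stack.
#' @return A numeric matrix of class `fret_kymograph` (distance x time)
#'   with calibration and the source line stored as attributes.
#' @export
build_kymograph <- function(movie, line, pixel_size_um = NULL,
                            frame_interval_s = NULL, channel = NULL) {
  if (inherits(movie, "fret_stack")) {
    pixel_size_um <- pixel_size_um %||% movie$pixel_size_um
    frame_interval_s <- frame_interval_s %||% movie$frame_interval_s
    movie <- movie$channels[[channel %||% names(movie$channels)[1]]]
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_s)) {
    abort("Calibration (`pixel_size_um`, `frame_interval_s`) is required.")
  }
  h <- dim(movie)[1]; w <- dim(movie)[2]; n_t <- dim(movie)[3]
  len <- sqrt((line$x1 - line$x0)^2 + (line$y1 - line$y0)^2)
  n_s <- floor(len) + 1L
  ts <- seq(0, 1, length.out = n_s)
  px <- round(line$x0 + ts * (line$x1 - line$x0))
  py <- round(line$y0 + ts * (line$y1 - line$y0))
  if (any(px < 1 | px > w | py < 1 | py > h)) {
    abort("Line exits the image bounds.")
  }
  kymo <- matrix(0, nrow = n_s, ncol = n_t)
  for (t in seq_len(n_t)) {
    kymo[, t] <- movie[, , t][cbind(py, px)]
  }
  structure(kymo, class = c("fret_kymograph", "matrix", "array"),
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            line = as.list(line))
}

edge_positions <- function(kymo, side) {
  n_t <- ncol(kymo)
  edge <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    fg <- which(kymo[, t] > 0.5)
    if (length(fg)) {
      edge[t] <- if (side == "left") min(fg) else max(fg)
    }
  }
  if (anyNA(edge)) {
    if (all(is.na(edge))) abort("Kymograph has no foreground in any frame.")
    warn("Frames without foreground on the line; edge interpolated from neighbouring frames.")
    ok <- which(!is.na(edge))
    edge <- round(approx(ok, edge[ok], xout = seq_len(n_t), rule = 2)$y)
  }
  edge
}

#' Detect protrusion events on a mask kymograph
#'
#' Tracks the outermost foreground pixel at each end of the line per frame,
#' subtracts the baseline edge position (median over the pre-stimulus
#' frames), and reports each maximal run of frames whose outward edge
#' displacement is at least `min_extension_um` as a protrusion event with
#' its peak extension (micrometres) and persistence (minutes). Events
#' shorter than `min_persistence_min` are discarded.
#'
#' @param kymo A binary [build_kymograph()] result from a mask movie.
#' @param stim_index Last pre-stimulus frame; frames `1:stim_index` define
#'   the baseline edge.
#' @param min_extension_um Minimum outward displacement to count as
#'   protruding.
#' @param min_persistence_min Minimum event duration.
#' @param cell_id Optional identifier copied onto the events.
#' @return A tibble of events: `cell_id`, `side` (`"left"` = start of the
#'   line), `onset_min`, `end_min`, `persistence_min`, `max_extension_um`,
#'   `max_extension_px`.
#' @export
detect_protrusions <- function(kymo, stim_index = 1L, min_extension_um = 1,
                               min_persistence_min = 1, cell_id = NA_character_) {
  stopifnot(inherits(kymo, "fret_kymograph"))
  if (!all(kymo %in% c(0, 1))) {
    abort("Protrusion detection requires a binary (mask-derived) kymograph.")
  }
  px_um <- attr(kymo, "pixel_size_um")
  dt_min <- attr(kymo, "frame_interval_s") / 60
  n_t <- ncol(kymo)
  check_stim_index(stim_index, n_t)
  times <- (seq_len(n_t) - 1) * dt_min
  out <- list()
  for (side in c("left", "right")) {
    edge <- edge_positions(kymo, side)
    baseline <- median(edge[1:stim_index])
    disp_px <- if (side == "left") baseline - edge else edge - baseline
    disp_um <- disp_px * px_um
    active <- disp_um >= min_extension_um
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      persistence <- (i1 - i0 + 1L) * dt_min
      if (persistence < min_persistence_min) next
      out[[length(out) + 1L]] <- tibble::tibble(
        cell_id = cell_id, side = side,
        onset_min = times[i0], end_min = times[i0] + persistence,
        persistence_min = persistence,
        max_extension_um = max(disp_um[i0:i1]),
        max_extension_px = max(disp_px[i0:i1]))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(cell_id = character(), side = character(),
                          onset_min = numeric(), end_min = numeric(),
                          persistence_min = numeric(),
                          max_extension_um = numeric(),
                          max_extension_px = numeric()))
  }
  purrr::list_rbind(out)
}

#' Classify a population by morphology and protrusion behaviour
#'
#' Summarizes, per condition, the fraction of round cells (minor:major axis
#' ratio above `ratio_high`), elongated cells (ratio below `ratio_low`),
#' cells with at least one protrusion longer than `len_thr_um`, and — among
#' those — the fraction whose long protrusions persist beyond
#' `time_thr_min`.
#'
#' @param morphology Tibble with `cell_id`, `axis_ratio` and optionally
#'   `condition` (one row per cell; defines the cell universe).
#' @param events Tibble of protrusion events (`cell_id`,
#'   `max_extension_um`, `persistence_min`); cells absent from it count as
#'   protrusion-free.
#' @param ratio_high,ratio_low Roundness thresholds.
#' @param len_thr_um,time_thr_min Protrusion length and persistence
#'   thresholds.
#' @return A tibble, one row per condition: `n_cells`, `frac_round`,
#'   `frac_elongated`, `frac_long_protrusion`, `frac_long_persistent`
#'   (NA when no cell has a long protrusion).
#' @export
classify_population <- function(morphology, events = NULL, ratio_high = 0.8,
                                ratio_low = 0.6, len_thr_um = 5,
                                time_thr_min = 15) {
  stopifnot(all(c("cell_id", "axis_ratio") %in% names(morphology)))
  if (nrow(morphology) == 0L) abort("Empty condition: no cells to classify.")
  if (is.null(events)) {
    events <- tibble::tibble(cell_id = character(), max_extension_um = numeric(),
                             persistence_min = numeric())
  }
  if (!"condition" %in% names(morphology)) morphology$condition <- "all"
  per_cell_events <- events |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      has_long = any(.data$max_extension_um > len_thr_um),
      has_long_persistent = any(.data$max_extension_um > len_thr_um &
                                  .data$persistence_min > time_thr_min),
      .groups = "drop")
  morphology |>
    dplyr::left_join(per_cell_events, by = "cell_id") |>
    dplyr::mutate(has_long = dplyr::coalesce(.data$has_long, FALSE),
                  has_long_persistent = dplyr::coalesce(.data$has_long_persistent, FALSE)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      frac_round = mean(.data$axis_ratio > ratio_high),
      frac_elongated = mean(.data$axis_ratio < ratio_low),
      frac_long_protrusion = mean(.data$has_long),
      frac_long_persistent = ifelse(any(.data$has_long),
                                    sum(.data$has_long_persistent) / sum(.data$has_long),
                                    NA_real_),
      .groups = "drop")
}
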