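#' Construct a channelled image stack
#'
#' A stack holds one `H x W x T` array of non-negative counts per channel
#' plus the physical calibration (pixel size and frame interval) that every
#' downstream distance and time measurement uses.
#'
#' @param channels Named list of numeric arrays, all `H x W x T` with
#'   identical dimensions.
#' @param pixel_size_um Pixel size, micrometres per pixel (> 0).
#' @param frame_interval_s Frame interval, seconds (> 0).
#' @return A list of class `fret_stack`.
#' @export
fret_stack <- function(channels, pixel_size_um, frame_interval_s) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    abort("`channels` must be a named list of arrays.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    abort("Each channel must be a 3-D array (height x width x frames).")
  }
  if (length(unique(lapply(dims, identity))) != 1L) {
    abort("All channels must share the same height, width and frame count.")
  }
  if (pixel_size_um <= 0 || frame_interval_s <= 0) {
    abort("Calibration fields must be positive.")
  }
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "fret_stack")
}

#' @export
print.fret_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<fret_stack> %d x %d px, %d frames, channels: %s\n  %.3g um/px, %.3g s/frame\n",
    d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
    x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Dimensions of a stack
#' @param stack A [fret_stack()].
#' @return Integer vector `(height, width, frames)`.
#' @export
stack_dim <- function(stack) dim(stack$channels[[1]])

#' Number of frames in a stack
#' @param stack A [fret_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$channels[[1]])[3]

#' Frame times of a stack in minutes
#' @param stack A [fret_stack()].
#' @return Numeric vector of frame times (minutes, first frame at 0).
#' @export
stack_times_min <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s / 60
}

#' Construct a region-of-interest set
#'
#' Holds the single cell-free background region plus one region per cell,
#' all as logical masks matching the stack dimensions. The background must
#' be disjoint from every cell region and every region non-empty.
#'
#' @param background Logical `H x W` matrix marking the cell-free region.
#' @param cells Named list of logical `H x W` matrices, one per cell.
#' @return A list of class `fret_rois`.
#' @export
fret_rois <- function(background, cells) {
  if (!is.matrix(background) || !is.logical(background)) {
    abort("`background` must be a logical matrix.")
  }
  if (sum(background) == 0L) abort("Background region is empty.")
  if (is.null(names(cells)) || any(names(cells) == "")) {
    abort("`cells` must be a named list of masks.")
  }
  for (id in names(cells)) {
    m <- cells[[id]]
    if (!identical(dim(m), dim(background))) {
      abort("All region masks must share the stack's height and width.")
    }
    if (sum(m) == 0L) abort(sprintf("Cell region '%s' is empty.", id))
    if (any(m & background)) {
      abort(sprintf("Background region overlaps cell region '%s'.", id))
    }
  }
  structure(list(background = background, cells = cells),
            class = "fret_rois")
}

# Fixed full-scale used when encoding counts into 16-bit TIFF pages.
TIFF_FULL_SCALE <- 65535

#' Write a stack as one multi-page TIFF per channel
#'
#' Pages are frame-major. Counts are stored as 16-bit integers against a
#' fixed full scale of 65535, so integer counts up to 65535 round-trip
#' exactly; fractional values are quantized to 1/65535.
#'
#' @param stack A [fret_stack()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; files are `<prefix>_<channel>.tif`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  stopifnot(inherits(stack, "fret_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(vapply(stack$channels, max, 1))
  if (mx > TIFF_FULL_SCALE) {
    abort(sprintf("Counts exceed the 16-bit full scale (%d).", TIFF_FULL_SCALE))
  }
  paths <- vapply(names(stack$channels), function(ch) {
    arr <- stack$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(t) arr[, , t] / TIFF_FULL_SCALE)
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    path
  }, character(1))
  invisible(paths)
}

#' Read a two-channel time-lapse stack from TIFF files
#'
#' Accepts one multi-page TIFF per channel (any number of channels >= 1).
#' All channels must agree on height, width and frame count; the physical
#' calibration must be supplied because plain TIFF carries none.
#'
#' @param paths Named character vector of TIFF paths; names become channel
#'   names.
#' @param pixel_size_um,frame_interval_s Physical calibration.
#' @return A [fret_stack()] with counts restored to their 16-bit scale.
#' @export
read_stack <- function(paths, pixel_size_um, frame_interval_s) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be named by channel.")
  }
  if (missing(pixel_size_um) || missing(frame_interval_s)) {
    abort("Calibration (`pixel_size_um`, `frame_interval_s`) is required.")
  }
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (t in seq_along(pages)) {
      pg <- pages[[t]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grey-stored-as-RGB
      arr[, , t] <- pg * TIFF_FULL_SCALE
    }
    arr
  })
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) {
    abort("Channel files disagree on dimensions or frame count.")
  }
  fret_stack(channels, pixel_size_um, frame_interval_s)
}

#' Write a binary mask movie as an 8-bit multi-page TIFF
#' @param movie Logical or 0/1 numeric `H x W x T` array.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_movie <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie)[3]), function(t) {
    m <- movie[, , t]
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask movie from a multi-page TIFF
#' @param path TIFF path.
#' @return A 0/1 numeric `H x W x T` array.
#' @export
read_mask_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]])
  arr
}
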