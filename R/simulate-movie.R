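ellipse_mask <- function(h, w, cx, cy, a, b) {
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

#' Simulate a segmentation-mask movie with programmed protrusions
#'
#' Renders an elliptical cell (major axis horizontal) and, for each
#' protrusion specification, extends the mask along the major axis on the
#' stated side by `round(extension_um / pixel_size_um)` pixels for every
#' frame whose time t satisfies `onset_min <= t < end_min`; outside that
#' window the boundary returns exactly to the baseline ellipse. The movie
#' is the ground truth for kymograph-based protrusion quantification.
#'
#' @param base_axes_px Semi-axes `c(a, b)` of the cell in pixels,
#'   `a >= b` (a along x).
#' @param protrusions Tibble with columns `onset_min`, `end_min`,
#'   `extension_um`, `side` (`"left"` or `"right"`); may have zero rows.
#' @param n_frames Number of frames.
#' @param frame_interval_s Frame interval, seconds.
#' @param pixel_size_um Pixel size, micrometres.
#' @param dim Optional `c(h, w)`; by default sized to fit the cell plus the
#'   largest programmed extension with clearance.
#' @param finger_halfwidth_px Half-width of the protruding finger, pixels.
#' @param seed Accepted for interface symmetry with the other generators;
#'   mask rendering is deterministic.
#' @return A list: `movie` (0/1 array `H x W x T`), `events` (ground-truth
#'   tibble with realized `extension_px`, `extension_um`, `persistence_min`),
#'   `pixel_size_um`, `frame_interval_s`, `center`, `base_axes_px`.
#' @examples
#' spec <- tibble::tibble(onset_min = 2, end_min = 22, extension_um = 6,
#'                        side = "right")
#' mv <- simulate_protrusion_movie(c(40, 30), spec, n_frames = 60)
#' @export
simulate_protrusion_movie <- function(base_axes_px = c(40, 30),
                                      protrusions = NULL,
                                      n_frames = 90L, frame_interval_s = 30,
                                      pixel_size_um = 0.5, dim = NULL,
                                      finger_halfwidth_px = 2L, seed = NULL) {
  a <- base_axes_px[1]; b <- base_axes_px[2]
  if (a < b) abort("Major semi-axis must be >= minor semi-axis (`a >= b`).")
  if (is.null(protrusions)) {
    protrusions <- tibble::tibble(onset_min = numeric(), end_min = numeric(),
                                  extension_um = numeric(), side = character())
  }
  if (nrow(protrusions)) {
    stopifnot(all(c("onset_min", "end_min", "extension_um", "side") %in%
                    names(protrusions)))
    if (any(protrusions$end_min <= protrusions$onset_min)) {
      abort("Each protrusion needs `end_min > onset_min`.")
    }
    if (any(protrusions$extension_um <= 0)) {
      abort("Protrusion extensions must be positive.")
    }
    if (!all(protrusions$side %in% c("left", "right"))) {
      abort("`side` must be 'left' or 'right'.")
    }
    for (s in c("left", "right")) {
      ev <- protrusions[protrusions$side == s, ]
      if (nrow(ev) > 1) {
        ev <- ev[order(ev$onset_min), ]
        if (any(ev$onset_min[-1] < ev$end_min[-nrow(ev)])) {
          abort(sprintf("Protrusions on the %s side overlap in time.", s))
        }
      }
    }
  }
  ext_px <- as.integer(round(protrusions$extension_um / pixel_size_um))
  max_ext <- if (length(ext_px)) max(ext_px) else 0L
  if (is.null(dim)) {
    dim <- c(2L * ceiling(b) + 11L, 2L * (ceiling(a) + max_ext) + 11L)
  }
  h <- dim[1]; w <- dim[2]
  cx <- (w + 1) %/% 2; cy <- (h + 1) %/% 2
  tip_r <- cx + floor(a); tip_l <- cx - floor(a)
  if (any(tip_r + ext_px[protrusions$side == "right"] > w - 1) ||
      any(tip_l - ext_px[protrusions$side == "left"] < 2) ||
      tip_l < 2 || tip_r > w - 1 || cy - b < 2 || cy + b > h - 1) {
    abort("A protrusion (or the cell) exits the field of view.")
  }

  base <- ellipse_mask(h, w, cx, cy, a, b)
  rows <- (cy - finger_halfwidth_px):(cy + finger_halfwidth_px)
  times <- (seq_len(n_frames) - 1) * frame_interval_s / 60
  movie <- array(0, dim = c(h, w, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- base
    if (nrow(protrusions)) {
      active <- which(protrusions$onset_min <= times[t] &
                        times[t] < protrusions$end_min)
      for (k in active) {
        cols <- if (protrusions$side[k] == "right") {
          (tip_r + 1):(tip_r + ext_px[k])
        } else {
          (tip_l - ext_px[k]):(tip_l - 1)
        }
        fr[rows, cols] <- TRUE
      }
    }
    movie[, , t] <- fr
  }
  events <- if (nrow(protrusions)) {
    n_active <- vapply(seq_len(nrow(protrusions)), function(k) {
      sum(protrusions$onset_min[k] <= times & times < protrusions$end_min[k])
    }, integer(1))
    tibble::tibble(side = protrusions$side,
                   onset_min = protrusions$onset_min,
                   end_min = protrusions$end_min,
                   extension_px = ext_px,
                   extension_um = ext_px * pixel_size_um,
                   n_frames = n_active,
                   persistence_min = n_active * frame_interval_s / 60)
  } else {
    tibble::tibble(side = character(), onset_min = numeric(),
                   end_min = numeric(), extension_px = integer(),
                   extension_um = numeric(), n_frames = integer(),
                   persistence_min = numeric())
  }
  list(movie = movie, events = events, pixel_size_um = pixel_size_um,
       frame_interval_s = frame_interval_s, center = c(x = cx, y = cy),
       base_axes_px = c(a = a, b = b))
}
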