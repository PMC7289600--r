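disk_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Simulate a two-channel ratiometric image stack with known ground truth
#'
#' Renders disk-shaped cells over a uniform cell-free background. Donor
#' pixels inside a cell carry `donor_level` counts above background; the
#' acceptor channel carries `donor_level * R_t` so that, after background
#' subtraction, the acceptor/donor region-mean ratio of each cell equals
#' its programmed trace exactly (up to the optional Gaussian read noise).
#'
#' @param traces Long tibble (`cell_id`, `time_min`, `ratio`) with one
#'   programmed ratio trace per cell in `layout`.
#' @param layout Tibble with columns `cell_id`, `x`, `y`, `r`: disk centres
#'   and radii in pixels (1-based pixel centres, x = column, y = row).
#' @param dim Stack height and width in pixels, `c(h, w)`.
#' @param donor_level Donor counts above background inside a cell.
#' @param background_level Uniform background counts (both channels).
#' @param read_noise_sd Additive Gaussian read noise sd, counts per pixel
#'   per frame.
#' @param pixel_size_um,frame_interval_s Physical calibration.
#' @param bg_margin_px Clearance between any cell and the background region.
#' @param seed Integer seed for the read noise.
#' @return A list: `stack` (a [fret_stack()] with channels `acceptor`,
#'   `donor`), `rois` (a [fret_rois()] with the cell-free background region
#'   and one region per cell), and `layout`.
#' @export
simulate_ratiometric_stack <- function(traces, layout, dim = c(96L, 96L),
                                       donor_level = 1000,
                                       background_level = 100,
                                       read_noise_sd = 0,
                                       pixel_size_um = 0.5,
                                       frame_interval_s = 30,
                                       bg_margin_px = 5, seed = NULL) {
  stopifnot(all(c("cell_id", "x", "y", "r") %in% names(layout)),
            all(c("cell_id", "time_min", "ratio") %in% names(traces)))
  h <- dim[1]; w <- dim[2]
  if (any(layout$x - layout$r < 1 | layout$x + layout$r > w |
          layout$y - layout$r < 1 | layout$y + layout$r > h)) {
    abort("Every cell disk must lie fully inside the frame.")
  }
  if (nrow(layout) > 1) {
    for (i in seq_len(nrow(layout) - 1)) for (j in (i + 1):nrow(layout)) {
      d <- sqrt((layout$x[i] - layout$x[j])^2 + (layout$y[i] - layout$y[j])^2)
      if (d <= layout$r[i] + layout$r[j]) abort("Cell disks overlap.")
    }
  }
  trace_tab <- split(traces, traces$cell_id)
  missing_tr <- setdiff(layout$cell_id, names(trace_tab))
  if (length(missing_tr)) {
    abort(sprintf("No trace supplied for cell(s): %s.",
                  paste(missing_tr, collapse = ", ")))
  }
  times <- sort(unique(traces$time_min))
  n_t <- length(times)

  masks <- lapply(seq_len(nrow(layout)), function(i) {
    disk_mask(h, w, layout$x[i], layout$y[i], layout$r[i])
  })
  names(masks) <- layout$cell_id
  clear <- lapply(seq_len(nrow(layout)), function(i) {
    disk_mask(h, w, layout$x[i], layout$y[i], layout$r[i] + bg_margin_px)
  })
  background <- !Reduce(`|`, clear, init = matrix(FALSE, h, w))
  if (sum(background) < 100L) {
    abort("Cell-free background region must contain at least 100 pixels.")
  }

  if (!is.null(seed)) withr::local_seed(seed)
  donor <- array(background_level, dim = c(h, w, n_t))
  acceptor <- array(background_level, dim = c(h, w, n_t))
  for (i in seq_len(nrow(layout))) {
    id <- layout$cell_id[i]
    tr <- trace_tab[[id]]
    r_t <- tr$ratio[match(times, tr$time_min)]
    if (anyNA(r_t)) abort(sprintf("Trace for '%s' does not cover every frame time.", id))
    m <- masks[[i]]
    for (t in seq_len(n_t)) {
      donor[, , t][m] <- background_level + donor_level
      acceptor[, , t][m] <- background_level + donor_level * r_t[t]
    }
  }
  if (read_noise_sd > 0) {
    donor <- donor + array(rnorm(length(donor), 0, read_noise_sd), dim(donor))
    acceptor <- acceptor + array(rnorm(length(acceptor), 0, read_noise_sd),
                                 dim(acceptor))
    donor[donor < 0] <- 0
    acceptor[acceptor < 0] <- 0
  }
  list(stack = fret_stack(list(acceptor = acceptor, donor = donor),
                          pixel_size_um, frame_interval_s),
       rois = fret_rois(background, masks),
       layout = layout)
}

#' Propagated standard deviation of an extracted region-mean ratio
#'
#' For a programmed ratio `R` extracted as the quotient of two
#' background-subtracted region means with additive pixel noise of sd
#' `read_noise_sd`, first-order error propagation over the cell region
#' (`n_px` pixels) and background region (`n_bg` pixels) gives the per-frame
#' sd of the extracted ratio. Used to test that extracted traces stay
#' within their predicted noise band.
#'
#' @param ratio Programmed ratio value(s).
#' @param donor_level Donor counts above background.
#' @param read_noise_sd Additive pixel noise sd.
#' @param n_px Pixels in the cell region.
#' @param n_bg Pixels in the background region.
#' @return Per-frame sd of the extracted ratio (same length as `ratio`).
#' @export
ratio_noise_sd <- function(ratio, donor_level, read_noise_sd, n_px, n_bg) {
  var_mean <- read_noise_sd^2 * (1 / n_px + 1 / n_bg)
  sqrt(var_mean * (1 + ratio^2)) / donor_level
}
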