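# Shared fixture builders. Everything is generated in code at test time.

noiseless_params <- function(model = "transient", amplitude = 0.5,
                             k_act = 0.6, k_dec = 0.06, baseline = 1.2) {
  kinetic_params(model, amplitude = amplitude, k_act = k_act, k_dec = k_dec,
                 baseline_r0 = baseline, noise_sd = 0)
}

# A small population of random responsive traces spanning both kinetic
# families, as a long tibble plus the stimulus index.
random_trace_set <- function(n_per_model = 25, seed = 1, noise_sd = 0.05) {
  pops <- lapply(c("transient", "sustained"), function(m) {
    simulate_population(n_per_model, m, params = list(noise_sd = noise_sd),
                        seed = seed + (m == "sustained"), condition = m)
  })
  traces <- dplyr::bind_rows(pops[[1]]$traces, pops[[2]]$traces)
  traces$cell_id <- paste(traces$condition, traces$cell_id, sep = "_")
  list(traces = traces, stim_index = pops[[1]]$stim_index)
}

# Rotated solid-ellipse mask built from the analytic inclusion test.
rotated_ellipse_mask <- function(h, w, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Piecewise-linear trace with a slope break at `t_break`.
piecewise_trace <- function(slope1, slope2, t_break = 10, t_end = 20,
                            dt = 0.5, noise_sd = 0, base = 1) {
  t <- seq(0, t_end, by = dt)
  r <- ifelse(t <= t_break,
              base + slope1 * t,
              base + slope1 * t_break + slope2 * (t - t_break))
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  fret_trace(t, r, stim_index = 1L)
}

pipeline_config <- function(out_dir, seed = 7) {
  list(
    seed = seed, out_dir = out_dir,
    input = list(type = "simulate", simulate = list(
      n_frames = 96L, frame_interval_s = 30, stim_index = 6L,
      conditions = list(
        list(name = "cytosol", model = "transient", n_cells = 15),
        list(name = "plasma_membrane", model = "sustained", n_cells = 15)))),
    qc = list(min_cells = 5))
}
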