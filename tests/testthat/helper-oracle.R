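# Independent brute-force re-implementation of the per-cell response
# metrics, written as plain loops over frames. Used as the oracle the
# vectorised/pipeline implementations are checked against.
oracle_metrics <- function(time_min, ratio, stim_index, t_eval_min = 40) {
  n <- length(ratio)
  r0 <- ratio[stim_index]
  t_stim <- time_min[stim_index]
  r_max <- -Inf
  r_min <- Inf
  t_max <- NA_real_
  for (i in (stim_index + 1):n) {
    if (ratio[i] > r_max) {
      r_max <- ratio[i]
      t_max <- time_min[i]
    }
    if (ratio[i] < r_min) r_min <- ratio[i]
  }
  t_eval <- t_stim + t_eval_min
  r40 <- NA_real_
  for (i in 2:n) {
    if (time_min[i - 1] <= t_eval && t_eval <= time_min[i]) {
      if (time_min[i] == t_eval) {
        r40 <- ratio[i]
      } else {
        w <- (t_eval - time_min[i - 1]) / (time_min[i] - time_min[i - 1])
        r40 <- ratio[i - 1] + w * (ratio[i] - ratio[i - 1])
      }
      break
    }
  }
  s40 <- if (r_max == r0) NaN else (r40 - r0) / (r_max - r0)
  t_half <- NA_real_
  if (r_max > r0) {
    level <- r0 + 0.5 * (r_max - r0)
    prev_t <- t_stim
    prev_r <- r0
    for (i in (stim_index + 1):n) {
      if (ratio[i] >= level) {
        t_half <- if (ratio[i] == prev_r) time_min[i] else
          prev_t + (level - prev_r) / (ratio[i] - prev_r) *
            (time_min[i] - prev_t)
        t_half <- t_half - t_stim
        break
      }
      prev_t <- time_min[i]
      prev_r <- ratio[i]
    }
  }
  list(sam40 = s40, max_over_baseline = (r_max - r0) / r0,
       max_dr_over_rmin = (r_max - r_min) / r_min,
       t_half_min = t_half, t_max_min = t_max - t_stim,
       r_max = r_max, r_min = r_min, r40 = r40)
}
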