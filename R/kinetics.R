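#' Kinetic parameters for a simulated biosensor response
#'
#' Two response families cover the trace shapes seen in compartment-targeted
#' ERK biosensor experiments: a `"transient"` rise-then-decay response
#' (cytosolic/nuclear-like) and a `"sustained"` slow-rise response that
#' plateaus or decays slowly (plasma-membrane-like).
#'
#' The noiseless fractional response f(tau) at time tau minutes after
#' stimulation is
#' \describe{
#'   \item{transient}{`f = A * c * (exp(-k_dec * tau) - exp(-k_act * tau))`,
#'     with `c` chosen so the peak equals `A`. Requires `k_act != k_dec`.}
#'   \item{sustained}{`f = A * (1 - exp(-k_act * tau)) * exp(-k_dec * tau)`;
#'     `k_dec = 0` gives a saturating plateau at `A`.}
#' }
#' The raw ratio is `R(t) = baseline_r0 * (1 + f + drift_per_min * t) *
#' (1 + eps_t)` with `eps_t ~ N(0, noise_sd^2)` i.i.d. per frame
#' (multiplicative noise, since a ratio of two shot-noise-limited region
#' means fluctuates on a relative scale).
#'
#' @param model `"transient"` or `"sustained"`.
#' @param amplitude Peak fractional response A (dimensionless; 0.745 means a
#'   74.5% maximal increase over baseline, the default calibration for a
#'   strong cytosolic ERK reporter response).
#' @param k_act Activation rate (1/min), > 0.
#' @param k_dec Decay rate (1/min), >= 0; 0 allowed for a sustained plateau.
#' @param baseline_r0 Raw pre-stimulus ratio, > 0.
#' @param noise_sd Multiplicative Gaussian noise sd per frame.
#' @param drift_per_min Linear baseline drift (fraction of baseline per
#'   minute).
#' @return A list of class `kinetic_params`.
#' @examples
#' kinetic_params("transient", amplitude = 0.5, k_act = 0.6, k_dec = 0.06)
#' @export
kinetic_params <- function(model = c("transient", "sustained"),
                           amplitude = 0.745, k_act = 0.2, k_dec = 0.04,
                           baseline_r0 = 1.2, noise_sd = 0.03,
                           drift_per_min = 0) {
  model <- match.arg(model)
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (k_act <= 0) abort("`k_act` must be > 0.")
  if (k_dec < 0) abort("`k_dec` must be >= 0.")
  if (baseline_r0 <= 0) abort("`baseline_r0` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (model == "transient" && k_act == k_dec) {
    abort("Transient kinetics require `k_act != k_dec` (the kernel is undefined at equality).")
  }
  structure(list(model = model, amplitude = amplitude, k_act = k_act,
                 k_dec = k_dec, baseline_r0 = baseline_r0,
                 noise_sd = noise_sd, drift_per_min = drift_per_min),
            class = "kinetic_params")
}

#' Noiseless fractional response kernel
#'
#' Evaluates the deterministic fractional response f(tau) of a parameter set
#' at times tau minutes after stimulation (f = 0 for tau <= 0).
#'
#' @param params A [kinetic_params()] object.
#' @param tau_min Numeric vector of times since stimulation, minutes.
#' @return Numeric vector of fractional responses.
#' @export
response_kernel <- function(params, tau_min) {
  stopifnot(inherits(params, "kinetic_params"))
  tau <- pmax(tau_min, 0)
  f <- with(params, {
    if (model == "transient") {
      if (k_dec == 0) {
        # limit of the difference-of-exponentials family: saturating rise
        amplitude * (1 - exp(-k_act * tau))
      } else {
        tau_peak <- log(k_act / k_dec) / (k_act - k_dec)
        cnorm <- 1 / (exp(-k_dec * tau_peak) - exp(-k_act * tau_peak))
        amplitude * cnorm * (exp(-k_dec * tau) - exp(-k_act * tau))
      }
    } else {
      amplitude * (1 - exp(-k_act * tau)) * exp(-k_dec * tau)
    }
  })
  f[tau_min <= 0] <- 0
  f
}

#' Peak time of the transient kernel
#'
#' Closed-form time of the maximum of the difference-of-exponentials
#' transient response: `ln(k_act / k_dec) / (k_act - k_dec)` minutes after
#' stimulation.
#'
#' @param params A [kinetic_params()] object with `model = "transient"` and
#'   `k_dec > 0`.
#' @return Peak time in minutes after stimulation.
#' @export
transient_peak_time <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model != "transient" || params$k_dec == 0) {
    abort("A finite peak time requires transient kinetics with `k_dec > 0`.")
  }
  log(params$k_act / params$k_dec) / (params$k_act - params$k_dec)
}

#' Simulate a single-cell ratio trace
#'
#' Generates a seeded ratiometric time course: a flat (optionally drifting)
#' baseline up to the stimulus frame, then the kinetic response kernel, with
#' multiplicative Gaussian noise per frame. Defaults emulate an EGF
#' time-lapse acquired every 30 s with 45 min of post-stimulus imaging.
#'
#' @param params A [kinetic_params()] object.
#' @param n_frames Total number of frames.
#' @param frame_interval_s Frame interval in seconds.
#' @param stim_index Index of the last pre-stimulus frame (>= 1,
#'   < `n_frames`).
#' @param seed Optional integer seed; identical arguments and seed give a
#'   bit-identical trace.
#' @param cell_id,condition Optional labels attached to the trace.
#' @return A `fret_trace` tibble with columns `time_min`, `ratio` and
#'   `ratio_true` (the noiseless ratio), and the stimulus index as an
#'   attribute.
#' @examples
#' p <- kinetic_params("sustained", k_act = 0.15, k_dec = 0, noise_sd = 0)
#' tr <- simulate_trace(p, n_frames = 96, stim_index = 6)
#' @export
simulate_trace <- function(params, n_frames = 96L, frame_interval_s = 30,
                           stim_index = 6L, seed = NULL, cell_id = NULL,
                           condition = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (n_frames <= stim_index || stim_index < 1L) {
    abort("Need `n_frames > stim_index >= 1`.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  time_min <- (seq_len(n_frames) - 1) * frame_interval_s / 60
  tau <- time_min - time_min[stim_index]
  f <- response_kernel(params, tau)
  r_true <- params$baseline_r0 *
    (1 + f + params$drift_per_min * time_min)
  eps <- if (params$noise_sd > 0) rnorm(n_frames, 0, params$noise_sd) else 0
  r <- r_true * (1 + eps)
  if (any(r_true <= 0)) abort("Drift drove the noiseless ratio non-positive.")
  r <- pmax(r, .Machine$double.eps)
  out <- fret_trace(time_min, r, stim_index = stim_index, cell_id = cell_id,
                    condition = condition)
  out$ratio_true <- r_true
  attr(out, "params") <- params
  out
}
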