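#' Sampling-gate pulse program
#'
#' Specification of the stochastic top-gate waveform that implements a neural
#' encoding algorithm:
#'
#' * `rate`: pulse amplitudes drawn i.i.d. from a Gaussian with mean `mu_tg`
#'   and standard deviation `sigma_tg` (defaults -2.5 V and 0.8 V).
#' * `count`: amplitudes ramp linearly in magnitude from `ramp_start` to
#'   `ramp_end` over the trial, with added zero-mean Gaussian noise of
#'   standard deviation `sigma_tg` (default 0.2 V); the spike count grows
#'   with the stimulus.
#' * `timing`: the mirror image of `count` (magnitude decreasing over time);
#'   stronger stimuli cross threshold earlier, and sampling is deactivated
#'   after the first spike.
#'
#' For `count`/`timing`, leaving the ramp endpoints `NULL` defers them until
#' encoding time, when they are computed from the device calibration so that
#' the ramp spans the sampling-gate voltages whose spiking thresholds cover
#' the 0-5 V stimulus window (see [default_ramp()]).
#'
#' @param mode Encoding algorithm: `"rate"`, `"count"` or `"timing"`.
#' @param mu_tg Gaussian mean of the sampling-pulse amplitude (V), rate mode.
#' @param sigma_tg Gaussian standard deviation (V); defaults to 0.8 in rate
#'   mode and 0.2 in count/timing mode.
#' @param ramp_start,ramp_end Ramp endpoints (V) for count/timing modes.
#' @param n_pulses Pulses per trial (default 32).
#' @param t_p Pulse duration in seconds (default 0.010).
#' @param n_trials Trials per stimulus level (default 16).
#' @param seed Integer root seed for all randomness under this program.
#' @param ramp_preset `"full"` calibrates the default ramp to span the full
#'   0-5 V stimulus window (counts cover roughly 0 to `n_pulses`); `"half"`
#'   spans it in the first half of the trial so the maximum count is about
#'   `n_pulses / 2`.
#' @return An object of class `pulse_program`.
#' @examples
#' pulse_program("rate")
#' pulse_program("count", seed = 7)
#' @export
pulse_program <- function(mode = c("rate", "count", "timing"),
                          mu_tg = -2.5,
                          sigma_tg = NULL,
                          ramp_start = NULL,
                          ramp_end = NULL,
                          n_pulses = 32L,
                          t_p = 0.010,
                          n_trials = 16L,
                          seed = 1L,
                          ramp_preset = c("full", "half")) {
  mode <- match.arg(mode)
  ramp_preset <- match.arg(ramp_preset)
  if (is.null(sigma_tg)) sigma_tg <- if (mode == "rate") 0.8 else 0.2
  if (sigma_tg < 0) stop("sigma_tg must be >= 0", call. = FALSE)
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  if (t_p <= 0) stop("t_p must be > 0", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (xor(is.null(ramp_start), is.null(ramp_end))) {
    stop("supply both ramp endpoints or neither", call. = FALSE)
  }
  if (!is.null(ramp_start)) {
    if (mode == "count" && abs(ramp_end) < abs(ramp_start)) {
      stop("count mode requires |ramp_end| >= |ramp_start|", call. = FALSE)
    }
    if (mode == "timing" && abs(ramp_end) > abs(ramp_start)) {
      stop("timing mode requires |ramp_end| <= |ramp_start|", call. = FALSE)
    }
  }
  structure(
    list(
      mode = mode, mu_tg = mu_tg, sigma_tg = sigma_tg,
      ramp_start = ramp_start, ramp_end = ramp_end,
      n_pulses = as.integer(n_pulses), t_p = t_p,
      n_trials = as.integer(n_trials), seed = as.integer(seed),
      ramp_preset = ramp_preset
    ),
    class = "pulse_program"
  )
}

#' @export
print.pulse_program <- function(x, ...) {
  cat(sprintf("<pulse_program: %s>\n", x$mode))
  if (x$mode == "rate") {
    cat(sprintf("  mu_tg: %.3g V, sigma_tg: %.3g V\n", x$mu_tg, x$sigma_tg))
  } else {
    rs <- if (is.null(x$ramp_start)) "auto" else sprintf("%.3g V", x$ramp_start)
    re <- if (is.null(x$ramp_end)) "auto" else sprintf("%.3g V", x$ramp_end)
    cat(sprintf("  ramp: %s -> %s (+noise sd %.3g V, preset %s)\n",
                rs, re, x$sigma_tg, x$ramp_preset))
  }
  cat(sprintf("  %d pulses x %d trials, t_p = %.3g s, seed = %d\n",
              x$n_pulses, x$n_trials, x$t_p, x$seed))
  invisible(x)
}

#' Default count/timing ramp endpoints from the device calibration
#'
#' Count mode ramps the sampling-gate magnitude from the voltage whose
#' spiking threshold sits at the bottom of the stimulus window (0 V) to the
#' voltage whose threshold sits at the top (5 V), plus one `sigma_tg` of
#' margin, so the spike count sweeps the full range of the trial. Timing
#' mode is the mirror image (most negative first).
#'
#' @param program A [pulse_program()] in count or timing mode.
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @param v_window Stimulus window to span, volts.
#' @return Numeric vector `c(ramp_start, ramp_end)`.
#' @export
default_ramp <- function(program, device, i_st, v_window = c(0, 5)) {
  v_lo <- spiking_threshold(v_window[1], i_st, device, terminal = "top")
  v_hi <- spiking_threshold(v_window[2], i_st, device, terminal = "top")
  if (program$ramp_preset == "half") {
    # span the window in the first half of the trial: maximum count ~ N/2
    v_hi <- v_lo + 2 * (v_hi - v_lo)
  }
  margin <- program$sigma_tg
  if (program$mode == "count") c(v_lo, v_hi - margin) else c(v_hi - margin, v_lo)
}

# Freeze deferred ramp endpoints into the program so repeated encoding calls
# do not re-run the threshold root-finder.
materialize_ramp <- function(program, device, i_st) {
  if (program$mode != "rate" && is.null(program$ramp_start)) {
    r <- default_ramp(program, device, i_st)
    program$ramp_start <- r[1]
    program$ramp_end <- r[2]
  }
  program
}

resolve_ramp <- function(program, device = NULL, i_st = NULL) {
  if (!is.null(program$ramp_start)) {
    return(c(program$ramp_start, program$ramp_end))
  }
  if (is.null(device) || is.null(i_st)) {
    stop("ramp endpoints are unset; supply `device` and `i_st` so the ",
         "default ramp can be derived from the calibration", call. = FALSE)
  }
  default_ramp(program, device, i_st)
}

#' Sample one trial of sampling-gate pulse amplitudes
#'
#' Draws the `n_pulses` top-gate amplitudes for one trial of the pulse
#' program. Deterministic given `(program$seed, unit, trial_index)`.
#'
#' @param program A [pulse_program()].
#' @param trial_index Trial number, `1..n_trials`.
#' @param device,i_st Device calibration and thresholding current; required
#'   only when a count/timing program has deferred (`NULL`) ramp endpoints.
#' @param unit Nonnegative integer identifying the encoded unit (e.g. a pixel
#'   index); separates substreams when many units share a program.
#' @return Numeric vector of `n_pulses` voltages.
#' @export
sample_pulse_train <- function(program, trial_index, device = NULL,
                               i_st = NULL, unit = 0L) {
  stopifnot(inherits(program, "pulse_program"))
  if (trial_index < 1 || trial_index > program$n_trials) {
    stop("trial_index must be in 1..n_trials", call. = FALSE)
  }
  n <- program$n_pulses
  base <- switch(program$mode,
    rate = rep(program$mu_tg, n),
    count = ,
    timing = {
      r <- resolve_ramp(program, device, i_st)
      if (n == 1L) r[1] else seq(r[1], r[2], length.out = n)
    }
  )
  noise <- with_substream(program$seed, unit, trial_index, 1L, code = {
    stats::rnorm(n, 0, program$sigma_tg)
  })
  base + noise
}
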