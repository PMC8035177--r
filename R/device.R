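#' Compact behavioral model of the dual-gated spike-encoder transistor
#'
#' Parameter container for the dual-gated FET used as the neural encoder.
#' The analog stimulus (presynaptic voltage, back gate) and the stochastic
#' sampling pulse (top gate) act on the channel through an effective gate
#' drive `v_eff = v_psv + cap_ratio * v_tg`; the postsynaptic drain current
#' follows a subthreshold exponential in `v_eff`, softly clamped in
#' log-current space between an off-state leakage floor and a saturation
#' ceiling.
#'
#' The default calibration is deterministic (two calls return identical
#' parameter sets) and reproduces the measured gate-capacitance ratio of 2.2
#' together with spiking-level currents in the 0.1-1 nA range, so that
#' per-spike encoding energies land in the picojoule regime.
#'
#' @param cap_ratio Dimensionless top-to-back gate capacitance ratio
#'   (the magnitude of the spiking-threshold slope versus sampling-gate
#'   voltage). Default 2.2.
#' @param v_on Back-gate voltage (V) at which the drain current equals
#'   `i_ref` with the sampling gate grounded.
#' @param ss Subthreshold swing in volts per decade of current, referenced to
#'   the back gate.
#' @param i_ref Current (A) at `v_psv = v_on`, `v_tg = 0`.
#' @param i_floor Off-state leakage floor (A).
#' @param i_sat Soft saturation ceiling (A).
#' @param c_tg Absolute top-gate capacitance (F), used by the capacitive term
#'   of the encoding-energy expression.
#' @param v_ds Drain bias (V).
#' @param readout_noise_frac Scale of the multiplicative log-normal current
#'   noise applied when currents are sampled with `noise = TRUE`.
#' @return An object of class `device_params`.
#' @examples
#' dev <- device_params()
#' psc_current(2.5, -2.5, dev)
#' @seealso [psc_current()], [spiking_threshold()]
#' @export
device_params <- function(cap_ratio = 2.2,
                          v_on = -3.0,
                          ss = 12.0,
                          i_ref = 5e-10,
                          i_floor = 1e-13,
                          i_sat = 2e-9,
                          c_tg = 3.2e-14,
                          v_ds = 1.0,
                          readout_noise_frac = 0.1) {
  p <- list(
    cap_ratio = cap_ratio, v_on = v_on, ss = ss, i_ref = i_ref,
    i_floor = i_floor, i_sat = i_sat, c_tg = c_tg, v_ds = v_ds,
    readout_noise_frac = readout_noise_frac
  )
  validate_device_params(p)
  structure(p, class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat("<device_params>\n")
  cat(sprintf("  cap_ratio (C_TG/C_BG): %.3f\n", x$cap_ratio))
  cat(sprintf("  v_on: %.3f V, ss: %.3f V/decade\n", x$v_on, x$ss))
  cat(sprintf(
    "  currents: floor %.3g A, ref %.3g A, sat %.3g A\n",
    x$i_floor, x$i_ref, x$i_sat
  ))
  cat(sprintf("  c_tg: %.3g F, v_ds: %.3g V, readout noise: %.3g\n",
              x$c_tg, x$v_ds, x$readout_noise_frac))
  invisible(x)
}

validate_device_params <- function(p) {
  num1 <- function(z) is.numeric(z) && length(z) == 1L && is.finite(z)
  if (!all(vapply(p, num1, logical(1)))) {
    stop("all device parameters must be finite scalars", call. = FALSE)
  }
  if (p$cap_ratio <= 0) stop("cap_ratio must be > 0", call. = FALSE)
  if (p$ss <= 0) stop("ss must be > 0", call. = FALSE)
  if (!(0 < p$i_floor && p$i_floor < p$i_ref && p$i_ref < p$i_sat)) {
    stop("currents must satisfy 0 < i_floor < i_ref < i_sat", call. = FALSE)
  }
  if (p$c_tg <= 0) stop("c_tg must be > 0", call. = FALSE)
  if (p$readout_noise_frac < 0) {
    stop("readout_noise_frac must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' Default device calibration
#'
#' Convenience wrapper returning [device_params()] with all defaults; provided
#' so scripts can name the calibration explicitly. Deterministic: repeated
#' calls return identical parameter sets.
#'
#' @return A `device_params` object.
#' @export
default_calibration <- function() device_params()

# Smooth clamp sharpness in log10-current space. Large enough that the
# calibration anchor I(v_on, 0) = i_ref holds to double precision whenever
# i_ref sits >= 0.5 decades away from both clamps.
CLAMP_SHARPNESS <- 40

softplus <- function(x, k = CLAMP_SHARPNESS) {
  # log(1 + exp(k*x))/k, overflow-safe
  ifelse(x > 0, x + log1p(exp(-k * x)) / k, log1p(exp(k * x)) / k)
}

log10_psc <- function(v_psv, v_tg, params) {
  v_eff <- v_psv + params$cap_ratio * v_tg
  l_raw <- log10(params$i_ref) + (v_eff - params$v_on) / params$ss
  l_lo <- log10(params$i_floor)
  l_hi <- log10(params$i_sat)
  l <- l_lo + softplus(l_raw - l_lo) # soft floor
  l_hi - softplus(l_hi - l)          # soft ceiling
}

#' Postsynaptic current of the neural encoder
#'
#' Drain current as a function of presynaptic (back-gate) voltage and
#' sampling (top-gate) voltage. Noise-free, the current is strictly
#' increasing in both gate voltages. With `noise = TRUE` the current is
#' multiplied by log-normal readout noise of scale
#' `params$readout_noise_frac`, drawn from the current RNG stream (callers
#' control reproducibility through seed substreams).
#'
#' @param v_psv Presynaptic voltage(s), volts.
#' @param v_tg Sampling-gate voltage(s), volts. Recycled against `v_psv`.
#' @param params A [device_params()] object.
#' @param noise Logical; apply multiplicative readout noise?
#' @return Current(s) in amperes.
#' @examples
#' dev <- device_params()
#' psc_current(dev$v_on, 0, dev) # equals dev$i_ref
#' @export
psc_current <- function(v_psv, v_tg, params = device_params(), noise = FALSE) {
  validate_device_params(params)
  if (!is.numeric(v_psv) || !is.numeric(v_tg) ||
      any(!is.finite(v_psv)) || any(!is.finite(v_tg))) {
    stop("gate voltages must be finite numerics", call. = FALSE)
  }
  i <- 10^log10_psc(v_psv, v_tg, params)
  if (noise && params$readout_noise_frac > 0) {
    i <- i * exp(stats::rnorm(length(i), 0, params$readout_noise_frac))
  }
  i
}

#' Spiking threshold of the encoder
#'
#' The spiking threshold is the presynaptic voltage at which the noise-free
#' drain current equals the thresholding current `i_st`. It is affine in the
#' sampling-gate voltage with slope `-cap_ratio`, independent of `i_st`. With
#' `terminal = "top"` the roles of the two gates are interchanged: the first
#' argument is the fixed back-gate voltage and the returned value is the
#' sampling-gate voltage at threshold (slope `-1/cap_ratio` versus `v_psv`).
#'
#' @param v_tg Sampling-gate voltage(s) (or back-gate voltage(s) when
#'   `terminal = "top"`), volts.
#' @param i_st Thresholding current, amperes; must lie strictly between the
#'   leakage floor and the saturation ceiling or no threshold exists.
#' @param params A [device_params()] object.
#' @param terminal Which terminal carries the stimulus being solved for.
#' @param tol Absolute root tolerance in volts.
#' @return Threshold voltage(s), volts.
#' @examples
#' dev <- device_params()
#' spiking_threshold(-2.5, 5e-10, dev) # mid-window by calibration
#' @export
spiking_threshold <- function(v_tg, i_st, params = device_params(),
                              terminal = c("back", "top"), tol = 1e-9) {
  validate_device_params(params)
  terminal <- match.arg(terminal)
  if (!is.numeric(v_tg) || any(!is.finite(v_tg))) {
    stop("v_tg must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(i_st) || length(i_st) != 1L || !is.finite(i_st) ||
      i_st <= params$i_floor || i_st >= params$i_sat) {
    stop("i_st must lie strictly between i_floor and i_sat; ",
         "the threshold does not exist otherwise", call. = FALSE)
  }
  l_target <- log10(i_st)
  f <- if (terminal == "back") {
    function(v, fixed) log10_psc(v, fixed, params) - l_target
  } else {
    function(v, fixed) log10_psc(fixed, v, params) - l_target
  }
  bracket <- c(-20, 20) * max(1, params$cap_ratio, 1 / params$cap_ratio)
  vapply(v_tg, function(fixed) {
    lo <- f(bracket[1], fixed)
    hi <- f(bracket[2], fixed)
    if (lo > 0 || hi < 0) {
      stop("threshold falls outside the search bracket [",
           bracket[1], ", ", bracket[2], "] V", call. = FALSE)
    }
    stats::uniroot(f, interval = bracket, fixed = fixed,
                   tol = tol, maxiter = 1000L)$root
  }, numeric(1))
}

#' Closed-form spiking threshold in the pure-exponential regime
#'
#' Analytic inversion `v_on - cap_ratio * v_tg + ss * log10(i_st / i_ref)`,
#' exact wherever the clamps are inactive. Used as an independent check on
#' the root-finder.
#'
#' @inheritParams spiking_threshold
#' @return Threshold voltage(s), volts.
#' @export
spiking_threshold_analytic <- function(v_tg, i_st, params = device_params()) {
  validate_device_params(params)
  params$v_on - params$cap_ratio * v_tg + params$ss * log10(i_st / params$i_ref)
}

#' Read / write a device calibration as a flat key-value file
#'
#' Human-readable `key = value` text, one parameter per line. Lines starting
#' with `#` are ignored on read.
#'
#' @param params A [device_params()] object.
#' @param path File path.
#' @return `write_device_config()` returns `path` invisibly;
#'   `read_device_config()` returns a `device_params` object.
#' @export
write_device_config <- function(params, path) {
  validate_device_params(params)
  lines <- c(
    "# spikecoder device calibration",
    sprintf("%s = %.17g", names(unclass(params)), unlist(params))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_device_config
#' @export
read_device_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  do.call(device_params, as.list(stats::setNames(vals, keys)))
}
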