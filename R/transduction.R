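#' Photodiode front-end parameters
#'
#' Parametric model of the neuromorphic sensor: a photodiode operating in
#' photovoltaic mode in parallel with a load resistor, converting LED
#' illuminance into the presynaptic voltage applied to the encoder. The
#' diode is an ideal current source (photocurrent proportional to
#' illuminance) in parallel with a Shockley diode; the operating point is the
#' intersection of that characteristic with the resistor load line.
#'
#' Illuminance is treated as an arbitrary linear unit; the defaults are
#' illustrative and chosen so that a three-decade illuminance sweep covers
#' the encoder's 0-5 V stimulus window.
#'
#' @param responsivity Photocurrent per unit illuminance (A per unit).
#' @param i_dark Reverse saturation current of the diode (A).
#' @param n_ideality Diode ideality factor (dimensionless).
#' @param v_thermal Thermal voltage scale (V).
#' @param r_load Load resistance (ohm).
#' @return An object of class `photodiode_params`.
#' @export
photodiode_params <- function(responsivity = 1e-6,
                              i_dark = 1e-9,
                              n_ideality = 2.0,
                              v_thermal = 0.3,
                              r_load = 5e4) {
  p <- list(
    responsivity = responsivity, i_dark = i_dark,
    n_ideality = n_ideality, v_thermal = v_thermal, r_load = r_load
  )
  if (!all(vapply(p, function(z) is.numeric(z) && length(z) == 1L &&
                    is.finite(z) && z > 0, logical(1)))) {
    stop("all photodiode parameters must be positive finite scalars",
         call. = FALSE)
  }
  structure(p, class = "photodiode_params")
}

#' @export
print.photodiode_params <- function(x, ...) {
  cat("<photodiode_params>\n")
  cat(sprintf("  responsivity: %.3g A/unit, i_dark: %.3g A\n",
              x$responsivity, x$i_dark))
  cat(sprintf("  n: %.3g, v_thermal: %.3g V, r_load: %.3g ohm\n",
              x$n_ideality, x$v_thermal, x$r_load))
  invisible(x)
}

#' Photodiode current
#'
#' Current delivered by the photodiode at terminal voltage `v_pd` under
#' illuminance `p_led`: photocurrent minus the forward diode term,
#' `responsivity * p_led - i_dark * (exp(v_pd / (n * v_t)) - 1)`. Strictly
#' decreasing in `v_pd`, strictly increasing in `p_led`.
#'
#' @param v_pd Diode terminal voltage(s), volts.
#' @param p_led Illuminance value(s), linear arbitrary units.
#' @param params A [photodiode_params()] object.
#' @return Current(s) in amperes.
#' @export
pd_current <- function(v_pd, p_led, params = photodiode_params()) {
  if (any(!is.finite(v_pd)) || any(!is.finite(p_led))) {
    stop("v_pd and p_led must be finite", call. = FALSE)
  }
  params$responsivity * p_led -
    params$i_dark * expm1(v_pd / (params$n_ideality * params$v_thermal))
}

#' Map illuminance to presynaptic voltage
#'
#' Solves the load-line equation `pd_current(v, p_led) = v / r_load` for the
#' operating voltage of the photodiode + load-resistor front-end. The result
#' is nonnegative, nondecreasing in illuminance, and bounded above by the
#' open-circuit voltage `n * v_t * log(1 + responsivity * p_led / i_dark)`.
#'
#' @param p_led Illuminance value(s), linear arbitrary units (>= 0).
#' @param params A [photodiode_params()] object.
#' @param tol Absolute root tolerance in volts.
#' @return Voltage(s) in volts.
#' @examples
#' illuminance_to_vpsv(c(0, 1, 10, 100))
#' @export
illuminance_to_vpsv <- function(p_led, params = photodiode_params(),
                                tol = 1e-9) {
  if (any(!is.finite(p_led)) || any(p_led < 0)) {
    stop("p_led must be finite and nonnegative", call. = FALSE)
  }
  nvt <- params$n_ideality * params$v_thermal
  vapply(p_led, function(p) {
    if (p == 0) return(0)
    v_oc <- nvt * log1p(params$responsivity * p / params$i_dark)
    f <- function(v) pd_current(v, p, params) - v / params$r_load
    # root lies in [0, v_oc]: f(0) > 0, f(v_oc) < 0
    stats::uniroot(f, interval = c(0, v_oc), tol = tol, maxiter = 1000L)$root
  }, numeric(1))
}

#' Transduce a table of illuminance values
#'
#' Tidy wrapper around [illuminance_to_vpsv()]: takes a data frame with an
#' illuminance column (or a bare numeric vector) and returns a tibble with
#' the corresponding presynaptic voltages appended.
#'
#' @param data A data frame containing `p_led`, or a numeric vector of
#'   illuminance values.
#' @param params A [photodiode_params()] object.
#' @return A tibble with columns `p_led` and `v_psv`.
#' @export
transduce <- function(data, params = photodiode_params()) {
  if (is.numeric(data)) data <- tibble::tibble(p_led = data)
  if (!"p_led" %in% names(data)) {
    stop("`data` must contain a `p_led` column", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                v_psv = illuminance_to_vpsv(.data$p_led, params))
}
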