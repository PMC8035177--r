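#' Spike train container
#'
#' Binary spike sequence from one encoding trial together with the per-pulse
#' sampling-gate amplitudes actually applied, the per-pulse drain currents,
#' and the active mask (in timing mode, pulses after the first spike are
#' deactivated and carry zero current and zero amplitude energy).
#'
#' @param spikes Logical vector, one entry per pulse.
#' @param currents Numeric vector of per-pulse drain currents (A).
#' @param amplitudes Numeric vector of applied sampling-gate voltages (V).
#' @param active Logical mask of applied pulses.
#' @param t_p Pulse duration (s).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spikes, currents, amplitudes, active, t_p) {
  n <- length(spikes)
  if (length(currents) != n || length(amplitudes) != n || length(active) != n) {
    stop("spike-train components must have equal length", call. = FALSE)
  }
  if (any(spikes & !active)) {
    stop("inactive pulses cannot spike", call. = FALSE)
  }
  structure(
    list(spikes = as.logical(spikes), currents = currents,
         amplitudes = amplitudes, active = as.logical(active), t_p = t_p),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d pulses, %d spikes, t_p = %.3g s>\n",
              length(x$spikes), sum(x$spikes), x$t_p))
  cat(" ", paste(ifelse(x$active, ifelse(x$spikes, "|", "."), " "),
                 collapse = ""), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.spike_train <- function(x, ...) {
  tibble::tibble(
    pulse = seq_along(x$spikes),
    time_s = (seq_along(x$spikes) - 1) * x$t_p,
    amplitude = x$amplitudes,
    current = x$currents,
    active = x$active,
    spike = x$spikes
  )
}

#' Encode one trial of an analog stimulus into a spike train
#'
#' Applies one trial of the sampling-pulse program to the device at stimulus
#' `v_psv`. Each active pulse produces a drain current (with multiplicative
#' readout noise unless `noise = FALSE`); a pulse spikes when its current
#' strictly exceeds the thresholding current `i_st`. In timing mode all
#' pulses after the first spike are deactivated. Reproducible given
#' `(program$seed, unit, trial_index)`.
#'
#' @param v_psv Stimulus voltage (V), scalar.
#' @param program A [pulse_program()].
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @param trial_index Trial number, `1..n_trials`.
#' @param unit Substream index for the encoded unit (e.g. pixel).
#' @param noise Logical; apply device readout noise?
#' @return A [spike_train()].
#' @examples
#' tr <- encode_trial(2.5, pulse_program("rate"), device_params(), 5e-10, 1)
#' count_from_spikes(tr)
#' @export
encode_trial <- function(v_psv, program, device, i_st, trial_index,
                         unit = 0L, noise = TRUE) {
  if (!is.numeric(v_psv) || length(v_psv) != 1L || !is.finite(v_psv)) {
    stop("v_psv must be a finite scalar", call. = FALSE)
  }
  amps <- sample_pulse_train(program, trial_index, device, i_st, unit)
  n <- program$n_pulses
  currents <- with_substream(program$seed, unit, trial_index, 2L, code = {
    psc_current(rep(v_psv, n), amps, device, noise = noise)
  })
  spikes <- currents > i_st
  active <- rep(TRUE, n)
  if (program$mode == "timing" && any(spikes)) {
    first <- which(spikes)[1]
    if (first < n) {
      off <- (first + 1L):n
      active[off] <- FALSE
      spikes[off] <- FALSE
      currents[off] <- 0
      amps[off] <- 0
    }
  }
  spike_train(spikes, currents, amps, active, program$t_p)
}

#' Firing rate from a spike train
#'
#' Inverse of the mean interspike interval, with intervals measured
#' center-to-center between consecutive spike pulses in units of `t_p`.
#' Trains with fewer than two spikes fall back to
#' `spike_count / (n_pulses * t_p)`, keeping the estimator defined (0 Hz for
#' silent trains).
#'
#' @param train A [spike_train()].
#' @return Firing rate in hertz.
#' @export
rate_from_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  idx <- which(train$spikes)
  if (length(idx) >= 2L) {
    1 / (mean(diff(idx)) * train$t_p)
  } else {
    length(idx) / (length(train$spikes) * train$t_p)
  }
}

#' Spike count from a spike train
#'
#' @param train A [spike_train()].
#' @return Number of spike pulses.
#' @export
count_from_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  sum(train$spikes)
}

#' First-spike latency from a spike train
#'
#' 1-based index of the first spiking pulse; trains with no spike return the
#' sentinel `n_pulses + 1`, which keeps the statistic monotone when averaged
#' over trials.
#'
#' @param train A [spike_train()].
#' @return Timestep index of the first spike.
#' @export
timing_from_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  idx <- which(train$spikes)
  if (length(idx) == 0L) length(train$spikes) + 1L else idx[1]
}

statistic_from_spikes <- function(train, mode) {
  switch(mode,
    rate = rate_from_spikes(train),
    count = as.numeric(count_from_spikes(train)),
    timing = as.numeric(timing_from_spikes(train))
  )
}

#' Closed-form spike probability of the rate encoder
#'
#' For rate-based encoding the per-pulse spike probability follows the
#' cumulative distribution of the Gaussian sampling amplitude: a pulse
#' spikes whenever its amplitude exceeds the sampling-gate voltage `v_tg*`
#' whose noise-free spiking threshold equals the stimulus, so
#' `p = pnorm((mu_tg - v_tg*) / sigma_tg)`. With `sigma_tg = 0` the transfer
#' function degenerates to a step.
#'
#' @param v_psv Stimulus voltage(s), volts.
#' @param program A rate-mode [pulse_program()].
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @return Spike probability in `[0, 1]`, one per stimulus level.
#' @examples
#' spike_probability(c(0, 2.5, 5), pulse_program("rate"), device_params(), 5e-10)
#' @export
spike_probability <- function(v_psv, program, device, i_st) {
  stopifnot(inherits(program, "pulse_program"))
  if (program$mode != "rate") {
    stop("spike_probability applies to rate-mode programs", call. = FALSE)
  }
  v_star <- spiking_threshold(v_psv, i_st, device, terminal = "top")
  if (program$sigma_tg == 0) {
    as.numeric(program$mu_tg > v_star)
  } else {
    stats::pnorm((program$mu_tg - v_star) / program$sigma_tg)
  }
}

#' Encoding energy of spike trains
#'
#' Energy of one trial,
#' `E = (1/N) * sum_i (1/2 * c_tg * v_tg_i^2 + i_psc_i * v_ds * t_p)`,
#' summed over the active pulses with `N = n_pulses` (inactive pulses carry
#' zero amplitude and current). With `per_spike = TRUE` the sum is divided
#' by the spike count instead of `N`; trains with zero spikes then return
#' `NA`. For a list of trains the per-trial energies are averaged.
#'
#' @param trains A [spike_train()] or a list of them.
#' @param device A [device_params()] object.
#' @param per_spike Normalize by spike count instead of pulse count?
#' @return Energy in joules.
#' @export
encoding_energy <- function(trains, device, per_spike = FALSE) {
  one <- function(tr) {
    stopifnot(inherits(tr, "spike_train"))
    terms <- 0.5 * device$c_tg * tr$amplitudes^2 +
      tr$currents * device$v_ds * tr$t_p
    total <- sum(terms[tr$active])
    if (per_spike) {
      k <- sum(tr$spikes)
      if (k == 0L) NA_real_ else total / k
    } else {
      total / length(tr$spikes)
    }
  }
  if (inherits(trains, "spike_train")) {
    one(trains)
  } else {
    mean(vapply(trains, one, numeric(1)), na.rm = TRUE)
  }
}

#' Encode a sweep of stimulus levels
#'
#' Runs the full encoding protocol (all trials of the pulse program) at each
#' stimulus level and summarizes the mode's statistic (firing rate, spike
#' count or first-spike timestep) and the per-trial encoding energy.
#' Deterministic given the program seed; every level uses its own seed
#' substream.
#'
#' @param levels Stimulus voltages (V).
#' @param program A [pulse_program()].
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @param noise Logical; apply device readout noise?
#' @param keep_trains Attach the per-trial spike trains as a list-column?
#' @return A tibble of class `encoding_sweep` with one row per level:
#'   `level`, `stat_mean`, `stat_sd` (across trials), `energy_mean` (J),
#'   `p_closed_form` (rate mode only), plus protocol metadata columns.
#' @examples
#' sw <- run_encoding_sweep(seq(0, 5, 2.5), pulse_program("rate", seed = 2),
#'                          device_params(), 5e-10)
#' sw$stat_mean
#' @export
run_encoding_sweep <- function(levels, program, device, i_st,
                               noise = TRUE, keep_trains = FALSE) {
  if (length(levels) == 0L) stop("`levels` must be nonempty", call. = FALSE)
  program <- materialize_ramp(program, device, i_st)
  rows <- purrr::imap(as.numeric(levels), function(v, li) {
    trains <- purrr::map(seq_len(program$n_trials), function(tr) {
      encode_trial(v, program, device, i_st, tr, unit = li, noise = noise)
    })
    stats_ <- vapply(trains, statistic_from_spikes, numeric(1),
                     mode = program$mode)
    out <- tibble::tibble(
      level = v,
      mode = program$mode,
      stat_mean = mean(stats_),
      stat_sd = stats::sd(stats_),
      energy_mean = mean(vapply(trains, encoding_energy, numeric(1),
                                device = device)),
      n_pulses = program$n_pulses,
      n_trials = program$n_trials,
      n_samples = program$n_pulses * program$n_trials
    )
    if (keep_trains) out$trains <- list(trains)
    out
  })
  out <- dplyr::bind_rows(rows)
  if (program$mode == "rate") {
    out <- dplyr::mutate(out,
      p_closed_form = spike_probability(.data$level, program, device, i_st),
      .after = "energy_mean")
  }
  class(out) <- c("encoding_sweep", class(out))
  attr(out, "i_st") <- i_st
  attr(out, "program") <- program
  out
}
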