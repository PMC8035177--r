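# Shared objects for the test suite. Everything is generated in code; no
# binary fixtures.

dev0 <- device_params()
IST0 <- 5e-10 # rate-mode thresholding current used throughout
LEVELS11 <- seq(0, 5, by = 0.5)

rate_prog <- function(seed = 1L, ...) pulse_program("rate", seed = seed, ...)

# Pooled spike fraction of the rate encoder at one stimulus level.
pooled_spike_fraction <- function(v, program, device, i_st, noise = TRUE) {
  spikes <- vapply(seq_len(program$n_trials), function(tr) {
    sum(encode_trial(v, program, device, i_st, tr, noise = noise)$spikes)
  }, numeric(1))
  sum(spikes) / (program$n_trials * program$n_pulses)
}

# Hand-built spike train with given spike pattern and constant current.
toy_train <- function(spikes, current = 5e-10, amplitude = -2.5,
                      t_p = 0.01) {
  n <- length(spikes)
  spike_train(as.logical(spikes), rep(current, n), rep(amplitude, n),
              rep(TRUE, n), t_p)
}
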