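test_that("a saturating stimulus makes every rate-mode pulse spike", {
  tr <- encode_trial(20, rate_prog(), dev0, IST0, 1, noise = FALSE)
  expect_true(all(tr$spikes))
  expect_equal(rate_from_spikes(tr), 100) # 32 spikes at t_p = 10 ms
})

test_that("rate statistic follows the inverse mean interspike interval", {
  expect_equal(rate_from_spikes(toy_train(rep(1, 32))), 100)
  expect_equal(rate_from_spikes(toy_train(rep(c(1, 0), 16))), 50)
  expect_equal(rate_from_spikes(toy_train(rep(0, 32))), 0)
  # one spike: fallback count/(N t_p)
  expect_equal(rate_from_spikes(toy_train(c(1, rep(0, 31)))), 1 / 0.32)
  # intervals are center-to-center in pulse slots
  s <- rep(0, 32); s[c(3, 7)] <- 1
  expect_equal(rate_from_spikes(toy_train(s)), 1 / (4 * 0.01))
})

test_that("count and timing statistics report spikes and first-spike latency", {
  expect_equal(count_from_spikes(toy_train(rep(1, 32))), 32)
  expect_equal(count_from_spikes(toy_train(rep(0, 32))), 0)
  expect_equal(timing_from_spikes(toy_train(c(0, 0, 1, rep(0, 29)))), 3)
  expect_equal(timing_from_spikes(toy_train(c(1, rep(0, 31)))), 1)
  expect_equal(timing_from_spikes(toy_train(rep(0, 32))), 33) # sentinel N+1
})

test_that("noise-free count encoding spikes exactly up to the ramp crossing", {
  prog <- pulse_program("count", sigma_tg = 0, seed = 1)
  v_levels <- c(1, 2.5, 4)
  r <- default_ramp(prog, dev0, IST0)
  ramp <- seq(r[1], r[2], length.out = prog$n_pulses)
  for (v in v_levels) {
    v_star <- spiking_threshold(v, IST0, dev0, terminal = "top")
    expected <- sum(ramp > v_star) # closed-form crossing index
    tr <- encode_trial(v, prog, dev0, IST0, 1, noise = FALSE)
    expect_equal(count_from_spikes(tr), expected)
    # crossing pulses are the leading ones
    expect_equal(which(tr$spikes), seq_len(expected))
  }
})

test_that("timing mode deactivates sampling after the first spike", {
  prog <- pulse_program("timing", seed = 3)
  # stimulus far above every ramp threshold: the first pulse must spike
  tr <- encode_trial(8, prog, dev0, IST0, 1, noise = FALSE)
  expect_equal(sum(tr$spikes), 1)
  expect_equal(which(tr$spikes), 1L)
  expect_false(any(tr$active[-1]))
  expect_true(all(tr$currents[-1] == 0))
  expect_true(all(tr$amplitudes[-1] == 0))
  # in-range stimuli: exactly one spike or none, never more
  counts <- vapply(seq(0, 5, 1), function(v) {
    sum(encode_trial(v, prog, dev0, IST0, 2)$spikes)
  }, numeric(1))
  expect_true(all(counts <= 1))
  # first-spike latency decreases with stimulus strength (noise-free)
  progn <- pulse_program("timing", sigma_tg = 0, seed = 3)
  lat <- vapply(seq(1, 5, 1), function(v) {
    timing_from_spikes(encode_trial(v, progn, dev0, IST0, 1, noise = FALSE))
  }, numeric(1))
  expect_true(all(diff(lat) <= 0))
})

test_that("closed-form spike probability matches its defining symmetries", {
  prog <- rate_prog()
  # stimulus at the threshold of the mean pulse: probability one half
  v_half <- spiking_threshold(prog$mu_tg, IST0, dev0)
  expect_equal(spike_probability(v_half, prog, dev0, IST0), 0.5)
  # degenerate sigma: step transfer function
  prog0 <- pulse_program("rate", sigma_tg = 0)
  expect_equal(spike_probability(c(v_half - 0.1, v_half + 0.1), prog0,
                                 dev0, IST0), c(0, 1))
  expect_error(spike_probability(2.5, pulse_program("count"), dev0, IST0),
               "rate-mode")
})

test_that("Monte-Carlo spike fractions agree with the closed form", {
  prog <- pulse_program("rate", n_trials = 64L, seed = 17L)
  n <- prog$n_trials * prog$n_pulses
  for (v in c(0.5, 2.5, 4.5)) {
    p <- spike_probability(v, prog, dev0, IST0)
    frac <- pooled_spike_fraction(v, prog, dev0, IST0, noise = FALSE)
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("encoding energy reproduces the hand-computed single-pulse value", {
  devE <- device_params(c_tg = 1e-15)
  tr <- spike_train(TRUE, 5e-10, -2.5, TRUE, 0.01)
  # 1/2 * 1 fF * 6.25 V^2 + 500 pA * 1 V * 10 ms = 5.003125 pJ
  expect_equal(encoding_energy(tr, devE), 5.003125e-12)
  expect_equal(encoding_energy(tr, devE, per_spike = TRUE), 5.003125e-12)
})

test_that("encoding energy handles floors, inactive pulses and zero spikes", {
  floor_train <- spike_train(rep(FALSE, 32), rep(dev0$i_floor, 32),
                             rep(0, 32), rep(TRUE, 32), 0.01)
  expect_equal(encoding_energy(floor_train, dev0),
               dev0$i_floor * dev0$v_ds * 0.01)
  expect_true(is.na(encoding_energy(floor_train, dev0, per_spike = TRUE)))
  # deactivated pulses contribute nothing
  tr <- spike_train(c(TRUE, FALSE), c(5e-10, 0), c(-2.5, 0),
                    c(TRUE, FALSE), 0.01)
  expect_equal(encoding_energy(tr, dev0),
               (0.5 * dev0$c_tg * 6.25 + 5e-10 * dev0$v_ds * 0.01) / 2)
})

test_that("sweeps carry the full sampling budget and are seed-reproducible", {
  sw <- run_encoding_sweep(c(0, 2.5, 5), rate_prog(seed = 4), dev0, IST0)
  expect_s3_class(sw, "encoding_sweep")
  expect_true(all(sw$n_samples == 512)) # 32 pulses x 16 trials
  expect_true(all(sw$stat_sd >= 0))
  sw2 <- run_encoding_sweep(c(0, 2.5, 5), rate_prog(seed = 4), dev0, IST0)
  expect_identical(sw$stat_mean, sw2$stat_mean)
  expect_error(run_encoding_sweep(numeric(0), rate_prog(), dev0, IST0),
               "nonempty")
})

test_that("timing-mode energy undercuts rate-mode energy at strong stimuli", {
  lv <- seq(2.5, 5, 0.5)
  swr <- run_encoding_sweep(lv, rate_prog(seed = 8), dev0, IST0)
  swt <- run_encoding_sweep(lv, pulse_program("timing", seed = 8), dev0, IST0)
  expect_true(all(swt$energy_mean <= swr$energy_mean))
})

test_that("sigma_tg trades dynamic range against encoding precision", {
  vfine <- seq(-6, 11, by = 0.01)
  span_and_slope <- function(sigma) {
    p <- spike_probability(vfine, pulse_program("rate", sigma_tg = sigma),
                           dev0, IST0)
    inside <- vfine[p >= 0.05 & p <= 0.95]
    c(span = diff(range(inside)), slope = max(diff(p)) / 0.01)
  }
  out <- vapply(c(0.4, 0.8, 1.6), span_and_slope, numeric(2))
  expect_true(all(diff(out["span", ]) > 0))  # span grows with sigma
  expect_true(all(diff(out["slope", ]) < 0)) # max slope shrinks with sigma
})

test_that("mu_tg shifts the high-precision window along the stimulus axis", {
  vfine <- seq(-6, 11, by = 0.01)
  centers <- vapply(c(-2, -2.5, -3), function(mu) {
    p <- spike_probability(vfine, pulse_program("rate", mu_tg = mu),
                           dev0, IST0)
    vfine[which.min(abs(p - 0.5))]
  }, numeric(1))
  expect_true(all(diff(centers) > 0)) # more negative mu -> higher window
})

test_that("raising the thresholding current suppresses spiking at every level", {
  p_lo <- spike_probability(LEVELS11, rate_prog(), dev0, 2e-10)
  p_hi <- spike_probability(LEVELS11, rate_prog(), dev0, 1e-9)
  expect_true(all(p_hi < p_lo))
  # and the simulated encoder sees it too
  prog <- rate_prog(seed = 12)
  f_lo <- pooled_spike_fraction(2.5, prog, dev0, 2e-10)
  f_hi <- pooled_spike_fraction(2.5, prog, dev0, 1e-9)
  expect_lt(f_hi, f_lo)
})

test_that("spike trains expose a tidy per-pulse record", {
  tr <- encode_trial(2.5, rate_prog(), dev0, IST0, 1)
  d <- tidy(tr)
  expect_s3_class(d, "tbl_df")
  expect_named(d, c("pulse", "time_s", "amplitude", "current", "active",
                    "spike"))
  expect_equal(nrow(d), 32)
  expect_error(spike_train(c(TRUE, TRUE), 1, 1, TRUE, 0.01), "equal length")
  expect_error(spike_train(TRUE, 1e-9, -2, FALSE, 0.01), "cannot spike")
})
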