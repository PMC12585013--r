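test_that("full-field noise has the advertised length, symmetry and determinism", {
  s <- gen_fullfield_noise(10, seed = 1L)
  expect_length(s$values, 600L)
  expect_true(all(s$values %in% c(-1, 1)))
  big <- gen_fullfield_noise(1e5 / 60, seed = 2L)
  n <- length(big$values)
  expect_lt(abs(mean(big$values)), 4 / sqrt(n))
  expect_identical(gen_fullfield_noise(10, seed = 3L)$values,
                   gen_fullfield_noise(10, seed = 3L)$values)
  expect_error(gen_fullfield_noise(10, fps = 0), "fps")
  expect_error(gen_fullfield_noise(-1), "duration")
})

test_that("checkerboard frames keep constant luminance and mix over time", {
  s <- gen_checkerboard(5, seed = 1L)
  expect_identical(dim(s$values), c(300L, 576L))
  expect_true(all(rowSums(s$values) == 0))          # 288 of 576 white
  expect_true(all(rowSums(s$values == 1) == 288L))
  expect_false(identical(s$values[1L, ], s$values[2L, ]))
  # per-pixel temporal mean: binomial bound at 1e4 frames
  long <- gen_checkerboard(1e4 / 60, seed = 5L)
  mu <- colMeans(long$values)
  expect_true(all(abs(mu) < 4 / sqrt(nrow(long$values))))
  expect_error(gen_checkerboard(5, ny = 3, nx = 3), "even")
})

test_that("flash protocol lays out OFF/ON/OFF/GRAY epochs on schedule", {
  p <- gen_flash_protocol(10)
  expect_identical(p$values, rep(c("OFF", "ON", "OFF", "GRAY"), 10L))
  expect_true(all(diff(p$frame_times) > 0))
  # 3 x 2 s epochs + 1 s ITI per trial, 10 trials -> 70 s total
  expect_equal(max(p$frame_times) + 1, 70)
  expect_error(gen_flash_protocol(0), "n_trials")
})

test_that("degenerate LN neurons produce the expected spike statistics", {
  stim <- gen_fullfield_noise(200, seed = 1L)
  # m = 0: homogeneous Poisson at baseline
  flat <- gt_neuron(biphasic_filter(), nl_slope = 0, baseline_rate = 10)
  spk <- gen_ln_spikes(stim, flat, seed = 2L)
  n <- length(spk$spike_times)
  expect_lt(abs(n - 2000) / sqrt(2000), 3)
  # no baseline, unreachable threshold: silence
  silent <- gt_neuron(biphasic_filter(), nl_slope = 5, nl_threshold = 1e9,
                      baseline_rate = 0)
  expect_length(gen_ln_spikes(stim, silent, seed = 3L)$spike_times, 0L)
  expect_error(gen_ln_spikes(stim, flat, state_on = TRUE), "length")
  short <- gen_fullfield_noise(0.1, seed = 1L)
  expect_error(gen_ln_spikes(short, flat), "longer than")
})

test_that("LN mean rate matches the rectified-Gaussian expectation", {
  # binary +-1 noise projected on a unit-norm filter is asymptotically N(0,1);
  # E rate = m * (phi(x0) - x0 * (1 - Phi(x0))) + baseline
  m <- 30; x0 <- 0.2; base <- 1
  nrn <- gt_neuron(biphasic_filter(), nl_slope = m, nl_threshold = x0,
                   baseline_rate = base)
  stim <- gen_fullfield_noise(600, seed = 7L)
  spk <- gen_ln_spikes(stim, nrn, seed = 8L)
  expected <- m * (dnorm(x0) - x0 * pnorm(x0, lower.tail = FALSE)) + base
  observed <- length(spk$spike_times) / 600
  expect_lt(abs(observed - expected) / expected, 0.05)
})

test_that("state gain scales the rectified drive only where the state is on", {
  nrn <- gt_neuron(biphasic_filter(), nl_slope = 30, nl_threshold = 0,
                   baseline_rate = 0, state_gain = 3)
  stim <- gen_fullfield_noise(600, seed = 9L)
  n <- length(stim$values)
  state <- rep(c(TRUE, FALSE), each = n / 2)
  spk <- gen_ln_spikes(stim, nrn, state_on = state, seed = 10L)
  t_half <- stim$frame_times[n / 2]
  r_on <- sum(spk$spike_times < t_half)
  r_off <- sum(spk$spike_times >= t_half)
  expect_gt(r_on / r_off, 2.5)
  expect_lt(r_on / r_off, 3.5)
})

test_that("behavior generator is reproducible and hits its running target", {
  b1 <- gen_behavior(600, seed = 5L)
  b2 <- gen_behavior(600, seed = 5L)
  expect_identical(b1$pupil_size, b2$pupil_size)
  expect_identical(b1$speed, b2$speed)
  frac <- mean(b1$speed > 2)
  expect_gt(frac, 0.25); expect_lt(frac, 0.35)      # target 0.30 +- 5 points
  # pupil is slow: autocorrelation at 1 s lag stays high
  ac <- cor(b1$pupil_size[-(1:30)], head(b1$pupil_size, -30))
  expect_gt(ac, 0.8)
  still <- gen_behavior(100, seed = 6L, run_fraction = 0)
  expect_true(all(still$speed == 0))
  expect_error(gen_behavior(0), "duration")
})

test_that("grating responses follow the tuning curve", {
  th <- seq(0, 315, by = 45) * pi / 180
  nrn <- gt_neuron(biphasic_filter(), tuning = 10 * (1 + cos(th)))
  g <- gen_grating_responses(nrn, n_trials = 200, seed = 1L)
  expect_identical(dim(g$rates), c(200L, 8L))
  expect_lt(max(abs(g$mean_rates - 10 * (1 + cos(th)))), 1.5)
  notuned <- gt_neuron(biphasic_filter())
  expect_error(gen_grating_responses(notuned), "tuning")
})

test_that("make_session assembles the full stimulus battery deterministically", {
  ms <- make_session(n_units = 3, seed = 1L, noise_s = 20, checker_s = 20,
                     n_flash_trials = 2)
  expect_length(ms$session$units, 3L)
  expect_length(ms$session$stimuli, 4L)
  expect_identical(vapply(ms$session$stimuli, `[[`, "", "kind"),
                   c("fullfield", "checkerboard", "flash", "grating"))
  ms2 <- make_session(n_units = 3, seed = 1L, noise_s = 20, checker_s = 20,
                      n_flash_trials = 2)
  expect_identical(ms$session$units[[2]]$spike_times,
                   ms2$session$units[[2]]$spike_times)
})
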