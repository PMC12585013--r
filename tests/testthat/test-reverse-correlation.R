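test_that("STA equals the naive per-spike oracle bit for bit", {
  stim <- gen_fullfield_noise(1e4 / 60, seed = 3L)
  nrn <- gt_neuron(biphasic_filter(), nl_slope = 30, nl_threshold = 0.1,
                   baseline_rate = 2)
  spk <- gen_ln_spikes(stim, nrn, seed = 3L)
  sta <- compute_sta(spk, stim)
  oracle <- brute_sta(spk$spike_times, stim$frame_times, stim$values, 30L)
  expect_identical(sta$C, oracle$C)
  expect_identical(sta$values, oracle$sta)
  # and under a state mask, with the same history-straddling drop rule
  mask <- rep(c(TRUE, FALSE), length.out = length(stim$values))
  mask[1000:4000] <- TRUE
  sta_m <- compute_sta(spk, stim, state_mask = mask)
  oracle_m <- brute_sta(spk$spike_times, stim$frame_times, stim$values, 30L,
                        state_mask = mask)
  expect_identical(sta_m$C, oracle_m$C)
  expect_identical(sta_m$values, oracle_m$sta)
})

test_that("constructed spike placements give a delta STA", {
  stim <- gen_fullfield_noise(60, seed = 4L)
  up <- which(stim$values == 1)
  up <- up[up + 5 <= length(stim$values)]
  spk <- spike_train("u", stim$frame_times[up + 5] + 1e-4, 0, 61)
  sta <- compute_sta(spk, stim)
  expect_equal(sta$values[6L], 1)           # lag 5: always white
  expect_lt(max(abs(sta$values[-6L])), 5 / sqrt(sta$C))
})

test_that("STA of a stimulus-independent unit stays within the null envelope", {
  stim <- gen_fullfield_noise(300, seed = 5L)
  spk <- poisson_train(35, 300, 6L)
  sta <- compute_sta(spk, stim)
  expect_gt(sta$C, 1e4)
  expect_true(all(abs(sta$values) < 5 / sqrt(sta$C)))
  expect_false(passes_sta_criterion(sta))
  masked <- rep(FALSE, length(stim$values))
  expect_error(compute_sta(spk, stim, state_mask = masked), "no spikes")
})

test_that("STA p-values follow the N(0, 1/C) null mapping", {
  C <- 2500L
  vals <- c(0, 1.96 / sqrt(C), 6.5 / sqrt(C))
  filt <- temporal_filter(vals, C = C)
  p <- sta_pvalues(filt)
  expect_identical(p[1L], 1)
  expect_equal(p[2L], 0.05, tolerance = 1e-3)
  expect_lt(p[3L], 1e-10)
  expect_true(passes_sta_criterion(temporal_filter(vals, C = C, p_values = p)))
  expect_false(passes_sta_criterion(temporal_filter(rep(0, 30), C = C)))
  # a significant bin beyond 200 ms does not rescue the filter
  late <- rep(0, 30); late[20L] <- 6.5 / sqrt(C)
  expect_false(passes_sta_criterion(temporal_filter(late, C = C)))
})

test_that("nonlinearity is flat for Poisson units and conserves spikes exactly", {
  stim <- gen_fullfield_noise(600, seed = 6L)
  spk <- poisson_train(10, 600, 7L)
  filt <- temporal_filter(biphasic_filter(), C = length(spk$spike_times))
  nl <- compute_nonlinearity(spk, stim, filt)
  counts <- bin_spikes(spk, stim$frame_times)
  retained <- sum(counts[-seq_len(29L)])
  expect_equal(sum(nl$rate_hz * nl$occupancy * nl$dt), retained,
               tolerance = 1e-9)
  occ <- nl$occupancy >= 200
  se <- sqrt(10 / (nl$occupancy[occ] * nl$dt))
  expect_true(all(abs(nl$rate_hz[occ] - 10) < 3 * se + 1e-9))
  expect_error(compute_nonlinearity(spk, stim, temporal_filter(rep(0, 30))),
               "zero-norm")
})

test_that("the generative rectified-linear nonlinearity is recovered", {
  m <- 30; x0 <- 0.2; base <- 1
  nrn <- gt_neuron(biphasic_filter(), nl_slope = m, nl_threshold = x0,
                   baseline_rate = base)
  stim <- gen_fullfield_noise(900, seed = 3L)
  spk <- gen_ln_spikes(stim, nrn, seed = 3L)
  sta <- compute_sta(spk, stim)
  nl <- compute_nonlinearity(spk, stim, sta)
  occ <- which(nl$occupancy >= 200)
  truth <- pmax(0, m * (nl$centers[occ] - x0)) + base
  big <- truth > 5    # compare on the responsive part of the curve
  expect_true(all(abs(nl$rate_hz[occ][big] - truth[big]) / truth[big] < 0.15))
  fit <- fit_halfwave_slope(nl, min_occupancy = 200L)
  expect_lt(abs(fit$slope - m) / m, 0.1)
})

test_that("gain ratio measures the imposed scaling and is equivariant", {
  edges <- seq(-1, 1, by = 0.1)
  n_bins <- length(edges) - 1L
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  rate <- pmax(0, 20 * centers)
  occ <- rep(500L, n_bins)
  before <- nonlinearity(edges, rate, occ, 1 / 60)
  after_same <- nonlinearity(edges, rate, occ, 1 / 60)
  expect_equal(gain_ratio(after_same, before), 0, tolerance = 1e-12)
  after_half <- nonlinearity(edges, 0.5 * rate, occ, 1 / 60)
  expect_equal(gain_ratio(after_half, before), -50, tolerance = 1e-12)
  # equivariance: scaling the after-curve by k scales (1 + change/100) by k
  g1 <- gain_ratio(after_half, before)
  after_scaled <- nonlinearity(edges, 0.5 * 1.8 * rate, occ, 1 / 60)
  g2 <- gain_ratio(after_scaled, before)
  expect_equal(1 + g2 / 100, 1.8 * (1 + g1 / 100), tolerance = 1e-12)
  sparse <- nonlinearity(edges, rate, rep(1L, n_bins), 1 / 60)
  expect_warning(out <- gain_ratio(sparse, before), "undefined")
  expect_true(is.na(out))
})

test_that("an imposed 50% gain drop is recovered from LN sessions", {
  gr <- vapply(1:5, function(s) {
    stim1 <- gen_fullfield_noise(300, seed = 1000L + s)
    stim2 <- gen_fullfield_noise(300, seed = 2000L + s)
    n1 <- gt_neuron(biphasic_filter(), nl_slope = 30, nl_threshold = 0.2,
                    baseline_rate = 2)
    n2 <- gt_neuron(biphasic_filter(), nl_slope = 15, nl_threshold = 0.2,
                    baseline_rate = 1)
    s1 <- gen_ln_spikes(stim1, n1, seed = 100L + s)
    s2 <- gen_ln_spikes(stim2, n2, seed = 200L + s)
    nl1 <- compute_nonlinearity(s1, stim1, compute_sta(s1, stim1))
    nl2 <- compute_nonlinearity(s2, stim2, compute_sta(s2, stim2))
    gain_ratio(nl2, nl1)
  }, 0)
  expect_true(all(gr > -60 & gr < -40))
})

test_that("spatial STA localizes a planted Gaussian receptive field", {
  rf <- list(cx = 20, cy = 9, sigma_long = 2, sigma_short = 1, theta = 0)
  nrn <- gt_neuron(biphasic_filter(), nl_slope = 40, nl_threshold = 0.1,
                   baseline_rate = 2, spatial_rf = rf)
  ck <- gen_checkerboard(600, seed = 11L)
  spk <- gen_ln_spikes(ck, nrn, seed = 12L)
  ss <- compute_spatial_sta(spk, ck)
  pk <- which(abs(ss$map) == max(abs(ss$map)), arr.ind = TRUE)
  expect_lte(abs(pk[1L] - rf$cy), 1)
  expect_lte(abs(pk[2L] - rf$cx), 1)
  # stimulus-independent unit: no pixel reaches the STA criterion
  null_spk <- poisson_train(30, 600, 13L)
  ssn <- compute_spatial_sta(null_spk, ck)
  p_min <- 2 * pnorm(max(abs(ssn$map)) * sqrt(ssn$C), lower.tail = FALSE)
  expect_gt(p_min, 1e-10)
  expect_error(compute_spatial_sta(spk, ck,
                                   stable_mask = rep(FALSE, nrow(ck$values))),
               "no spikes")
})
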