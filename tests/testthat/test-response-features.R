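test_that("DoG latency is exact on noiseless bumps and sign-symmetric", {
  t <- (0:29) / 60
  bump <- exp(-(t - 0.05)^2 / (2 * 0.012^2))
  filt <- temporal_filter(bump, C = 10000L)
  lat <- fit_dog_latency(filt, check_criterion = FALSE)
  expect_lt(abs(lat$latency_ms - 50), 1000 / 60)   # within one bin
  flipped <- temporal_filter(-bump, C = 10000L)
  lat2 <- fit_dog_latency(flipped, check_criterion = FALSE)
  expect_equal(lat2$latency_ms, lat$latency_ms, tolerance = 1)
  expect_error(fit_dog_latency(temporal_filter(rep(0, 30), C = 100L)),
               "criterion")
})

test_that("DoG latency of the model filter matches its raw extremum", {
  L <- canonical_filter()
  filt <- temporal_filter(L, C = 100000L)
  lat <- fit_dog_latency(filt, check_criterion = FALSE)
  raw_ms <- (which.max(abs(L)) - 1L) / 60 * 1000
  expect_lt(abs(lat$latency_ms - raw_ms), 1000 / 60)
})

test_that("spectral peak frequency obeys Fourier identities", {
  t <- (0:59) / 60
  sine6 <- temporal_filter(sin(2 * pi * 6 * t), C = 1000L)
  expect_lt(abs(spectral_peak_frequency(sine6) - 6), 0.06)
  # stretching the filter 2x in time halves the peak (dt doubled)
  stretched <- temporal_filter(sin(2 * pi * 6 * t), dt = 2 / 60, C = 1000L)
  expect_lt(abs(spectral_peak_frequency(stretched) - 3), 0.06)
  # frozen from a direct FFT of the closed-form model filter (1024-point pad)
  Lf <- temporal_filter(canonical_filter(), C = 1000L)
  expect_equal(spectral_peak_frequency(Lf), 2.8125, tolerance = 1e-9)
  expect_warning(out <- spectral_peak_frequency(temporal_filter(rep(1, 30))),
                 "flat")
  expect_true(is.na(out))
})

test_that("polarity index reflects peak/valley balance", {
  pos <- temporal_filter(c(0, 0.5, 1, 0.5, 0), C = 10L)
  expect_identical(polarity_index(pos), 1)
  odd <- temporal_filter(c(0, 1, 0, -1, 0), C = 10L)
  expect_identical(polarity_index(odd), 0)
  neg <- temporal_filter(-c(0, 0.5, 1, 0.5, 0), C = 10L)
  expect_identical(polarity_index(neg), -1)
  # antisymmetry under sign flip on random filters
  for (seed in 1:5) {
    v <- withr::with_seed(seed, rnorm(30))
    f <- temporal_filter(v, C = 10L)
    g <- temporal_filter(-v, C = 10L)
    expect_equal(polarity_index(f), -polarity_index(g), tolerance = 1e-12)
  }
  # frozen from direct evaluation of the closed-form model filter
  expect_equal(polarity_index(temporal_filter(canonical_filter(), C = 10L)),
               0.000675657754075, tolerance = 1e-9)
})

test_that("SNR separates reliable responses from noise", {
  sig <- 5 + 4 * sin(seq(0, 4 * pi, length.out = 120))
  ident <- matrix(rep(sig, 3), 3, byrow = TRUE)
  s <- snr(ident)
  expect_identical(s$snr, Inf)
  expect_true(s$selected)
  noisy <- withr::with_seed(2L, t(replicate(30, sig + rnorm(120, 0, 2))))
  s2 <- snr(noisy)
  expect_lt(abs(s2$snr - var(sig) / 4) / (var(sig) / 4), 0.2)
  # a constant offset shifts neither numerator nor denominator
  expect_equal(snr(noisy + 7)$snr, s2$snr, tolerance = 1e-12)
  # pure noise rarely crosses the selection threshold
  rejections <- sum(vapply(1:100, function(s) {
    m <- withr::with_seed(1000L + s, matrix(rnorm(10 * 120), 10))
    !snr(m)$selected
  }, NA))
  expect_gte(rejections, 95L)
})

test_that("flash analysis recovers polarity, latency and peak rate", {
  proto <- gen_flash_protocol(10)
  spikes <- withr::with_seed(1L, {
    unlist(lapply(0:9, function(tr) {
      t0 <- tr * 7
      c(t0 + runif(20, 0, 6) ,                       # background
        t0 + 2 + 0.040 + rnorm(120, 0, 0.008),       # burst 40 ms after ON
        t0 + 2 + runif(60, 0.2, 2))                  # sustained ON
    }))
  })
  spikes <- sort(spikes[spikes >= 0 & spikes < 70])
  fa <- flash_analysis(spike_train("on", spikes, 0, 70), proto)
  expect_gt(fa$on_off_index, 0)
  expect_lt(abs(fa$peak_latency_ms - 40), 5)
  expect_gt(fa$peak_rate_hz, 100)
  # an OFF cell is anchored at stimulus offset instead
  off_spikes <- sort(unlist(lapply(0:9, function(tr) {
    tr * 7 + 4 + 0.060 + abs(rnorm(80, 0, 0.01))
  })))
  fb <- flash_analysis(spike_train("off", off_spikes, 0, 70), proto)
  expect_lt(fb$on_off_index, 0)
  expect_lt(abs(fb$peak_latency_ms - 65), 20)
  # balanced cell: index 0
  bal <- sort(c(seq(2.05, 3.95, by = 0.1), seq(4.05, 5.95, by = 0.1),
                seq(9.05, 10.95, by = 0.1), seq(11.05, 12.95, by = 0.1)))
  fc <- flash_analysis(spike_train("bal", bal, 0, 70),
                       gen_flash_protocol(2))
  expect_equal(fc$on_off_index, 0, tolerance = 1e-12)
})

test_that("2-D Gaussian receptive-field fits are exact on clean maps", {
  gx <- rep(1:32, each = 18)
  gy <- rep(1:18, 32)
  map <- matrix(0.3 * exp(-0.5 * ((gx - 20) / 2)^2 - 0.5 * ((gy - 9) / 1)^2),
                18, 32)
  fit <- fit_rf(spatial_filter(map, 5L, 1000L))$fit
  expect_true(fit$converged)
  expect_equal(fit$rf_size, 3, tolerance = 1e-3)
  expect_equal(c(fit$cx, fit$cy), c(20, 9), tolerance = 1e-3)
  # isotropic case: orientation unidentifiable, size still stable
  iso <- matrix(exp(-((gx - 16)^2 + (gy - 9)^2) / (2 * 1.5^2)), 18, 32)
  fiso <- fit_rf(spatial_filter(iso, 5L, 1000L))$fit
  expect_equal(fiso$rf_size, 3, tolerance = 1e-3)
  # OFF-sign map fits with negative amplitude, same geometry
  foff <- fit_rf(spatial_filter(-map, 5L, 1000L))$fit
  expect_lt(foff$amp, 0)
  expect_equal(foff$rf_size, 3, tolerance = 1e-3)
})

test_that("receptive-field size survives the full checkerboard round trip", {
  rf <- list(cx = 14, cy = 10, sigma_long = 2, sigma_short = 1.5, theta = 0.4)
  nrn <- gt_neuron(biphasic_filter(), nl_slope = 40, nl_threshold = 0.1,
                   baseline_rate = 2, spatial_rf = rf)
  ck <- gen_checkerboard(900, seed = 21L)
  spk <- gen_ln_spikes(ck, nrn, seed = 22L)
  fit <- fit_rf(compute_spatial_sta(spk, ck))$fit
  truth <- rf$sigma_long + rf$sigma_short
  expect_lt(abs(fit$rf_size - truth) / truth, 0.15)
})

test_that("DS/OS indices match their closed forms", {
  th <- seq(0, 315, by = 45) * pi / 180
  delta <- rep(0, 8); delta[3L] <- 5
  expect_equal(ds_os_index(delta, alpha = 1), 1, tolerance = 1e-12)
  expect_equal(ds_os_index(delta, alpha = 2), 1, tolerance = 1e-12)
  expect_equal(ds_os_index(rep(3, 8), alpha = 1), 0, tolerance = 1e-12)
  expect_equal(ds_os_index(rep(3, 8), alpha = 2), 0, tolerance = 1e-12)
  expect_equal(ds_os_index(1 + cos(th - 0.7), alpha = 1), 0.5,
               tolerance = 1e-12)
  # scale invariance
  r <- withr::with_seed(4L, runif(8))
  expect_equal(ds_os_index(5 * r), ds_os_index(r), tolerance = 1e-12)
  expect_true(ds_os_index(r) >= 0 && ds_os_index(r) <= 1)
  expect_true(is.na(ds_os_index(rep(0, 8))))
  # flat tuning converges to 0 with trials
  flat <- gt_neuron(biphasic_filter(), tuning = rep(10, 8))
  g <- gen_grating_responses(flat, n_trials = 2000, seed = 5L)
  expect_lt(ds_os_index(g$mean_rates), 0.05)
})

test_that("functional typing recovers planted archetypes deterministically", {
  arche <- list(biphasic_filter(30, 2.5, 1), biphasic_filter(30, 5, 1),
                biphasic_filter(30, 9, 1), biphasic_filter(30, 2.5, -1),
                biphasic_filter(30, 5, -1), biphasic_filter(30, 9, -1))
  filters <- list(); truth <- integer()
  withr::with_seed(42L, {
    for (a in 1:6) for (r in 1:20) {
      filters[[length(filters) + 1L]] <-
        temporal_filter(arche[[a]] + rnorm(30, 0, 0.05), C = 1000L)
      truth[length(truth) + 1L] <- a
    }
  })
  cl <- classify_types(filters, seed = 9L)
  purity <- mean(vapply(1:6, function(a) {
    max(table(cl$labels[truth == a]))
  }, 0) / 20)
  expect_gte(purity, 0.95)
  expect_setequal(unique(cl$type),
                  c("fast ON", "ON", "slow ON", "fast OFF", "OFF", "slow OFF"))
  cl2 <- classify_types(filters, seed = 9L)
  expect_identical(cl$labels, cl2$labels)
  same <- replicate(10, temporal_filter(biphasic_filter(), C = 10L),
                    simplify = FALSE)
  expect_warning(deg <- classify_types(same, seed = 1L), "degenerate")
  expect_true(deg$degenerate)
  expect_error(classify_types(filters[1:3], k = 6L))
})
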