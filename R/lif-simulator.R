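# Integrate-and-fire neuron with Poisson (stochastic-threshold) spiking and
# refractoriness, and the gain x baseline parameter sweep re-analyzed with the
# same LN estimators used for recorded cells.

#' Simulator parameter set
#'
#' @param nT Filter length in bins (>= 2), default 25.
#' @param s_t Temporal spacing parameter of the log-time filter, default 1.5.
#' @param s_h Refractory time constant in bins, default 1.
#' @param G Multiplicative gain (> 0), default 1.
#' @param B Additive resting baseline (dimensionless), default 0.
#' @param stim_len Stimulus length in frames, default 1e6.
#' @param seed Integer seed.
#' @return An object of class `model_params`.
#' @export
model_params <- function(nT = 25L, s_t = 1.5, s_h = 1, G = 1, B = 0,
                         stim_len = 1e6L, seed = 1L) {
  stopifnot(nT >= 2L, G > 0, stim_len > nT, s_h > 0)
  structure(list(nT = as.integer(nT), s_t = s_t, s_h = s_h, G = G, B = B,
                 stim_len = as.integer(stim_len), seed = as.integer(seed)),
            class = "model_params")
}

#' Canonical model temporal filter
#'
#' A single-cycle sine on a logarithmic time axis:
#' `L(i) = sin(2*pi*(10^t_i - 1) / (10^s_t - 1))` with
#' `t_i = i * s_t / (nT - 1)`, i = 0..nT-1. The log warp stretches the early
#' (positive) lobe and compresses the late (negative) lobe, giving a biphasic
#' impulse response with unequal lobe widths.
#'
#' @inheritParams model_params
#' @return Numeric vector of length `nT`; `L(0) = L(nT-1) = 0`.
#' @export
canonical_filter <- function(nT = 25L, s_t = 1.5) {
  stopifnot(nT >= 2L)
  i <- seq_len(nT) - 1L
  t_i <- i * s_t / (nT - 1L)
  sin(2 * pi * (10^t_i - 1) / (10^s_t - 1))
}

#' Simulate the stochastic-threshold neuron
#'
#' The drive is `V(i) = G * (sum_j L(j) * S(i-j) + B)` where `S` is the
#' Gaussian white-noise stimulus normalized to a maximum absolute value of 1.
#' At each frame the neuron spikes iff the effective drive (drive plus the sum
#' of refractory kernels from past spikes) strictly exceeds an independent
#' uniform(0,1) threshold. Each spike contributes `-exp(-j / s_h)` for
#' `j = 0..5`, applied starting at the first bin after the spike (`refractory_offset
#' = 1`); `refractory_offset = 0` applies it from the spike bin itself for
#' sensitivity analyses, and `refractory = FALSE` disables it.
#'
#' @param params A [model_params].
#' @param stimulus Optional per-frame real stimulus; by default standard normal
#'   noise of length `params$stim_len` drawn under `params$seed`. Normalization
#'   by the maximum absolute value is applied here.
#' @param refractory Logical; include the refractory kernel.
#' @param refractory_offset 1 (default) or 0; bin offset of the kernel
#'   relative to the spike bin.
#' @return List with `spike_frames` (1-based frame indices), `spike_count`,
#'   `stimulus` (normalized), `drive` (V), and `params`.
#' @export
lif_simulate <- function(params, stimulus = NULL, refractory = TRUE,
                         refractory_offset = 1L) {
  stopifnot(inherits(params, "model_params"), refractory_offset %in% c(0L, 1L))
  if (is.null(stimulus)) {
    stimulus <- withr::with_seed(params$seed, rnorm(params$stim_len))
  }
  if (length(stimulus) <= params$nT) {
    stop("stimulus shorter than the filter", call. = FALSE)
  }
  stimulus <- stimulus / max(abs(stimulus))
  L <- canonical_filter(params$nT, params$s_t)
  V <- params$G * (as.numeric(stats::filter(stimulus, L, method = "convolution",
                                            sides = 1)) + params$B)
  V[seq_len(params$nT - 1L)] <- NA  # incomplete history: no spiking there
  n <- length(stimulus)
  kern <- -exp(-(0:5) / params$s_h)
  u <- withr::with_seed(params$seed + 1L, runif(n))
  ref <- numeric(n + 7L)  # slack so kernel writes never go out of bounds
  spk <- logical(n)
  if (refractory) {
    for (i in params$nT:n) {
      if (V[i] + ref[i] > u[i]) {
        spk[i] <- TRUE
        j0 <- i + refractory_offset
        ref[j0:(j0 + 5L)] <- ref[j0:(j0 + 5L)] + kern
      }
    }
  } else {
    idx <- params$nT:n
    spk[idx] <- V[idx] > u[idx]
  }
  frames <- which(spk)
  list(spike_frames = frames, spike_count = length(frames),
       stimulus = stimulus, drive = V, params = params)
}

# STA of a frame-indexed simulation over nT lag bins (lag 0 = spike frame).
sim_sta <- function(stimulus, spike_frames, n_lags) {
  keep <- spike_frames[spike_frames >= n_lags]
  C <- length(keep)
  if (C == 0L) stop("no spikes with complete stimulus history", call. = FALSE)
  sta <- vapply(0:(n_lags - 1L), function(k) sum(stimulus[keep - k]) / C, 0)
  list(sta = sta, C = C)
}

#' Run the gain x baseline sweep
#'
#' Simulates the model over the full grid `B in {-0.45, ..., +0.45} step 0.15`
#' by `G = 1.2^g, g = -3..+3` (49 cells), reusing one stimulus realization
#' across cells, and re-analyzes every spike train with the LN estimators:
#' STA over `nT` lags, difference-of-Gaussians peak latency, spectral peak
#' frequency, and the slope of the half-wave-rectified static nonlinearity.
#' Cells yielding fewer than `min_spikes` spikes have their estimated features
#' set to `NA` rather than raising.
#'
#' @param base A [model_params] providing nT, s_t, s_h, stim_len and the base
#'   seed (per-cell threshold seed = base seed + cell index).
#' @param min_spikes Minimum spikes for feature estimation, default 100.
#' @param bins_per_s Bin rate used to express latency in ms and frequency in
#'   Hz, default 60.
#' @return `data.frame` with one row per cell: B, g, G, spike_count,
#'   latency_bins, latency_ms, freq_hz, nl_slope.
#' @export
run_sweep <- function(base = model_params(), min_spikes = 100L, bins_per_s = 60) {
  stimulus <- withr::with_seed(base$seed, rnorm(base$stim_len))
  stimulus <- stimulus / max(abs(stimulus))
  grid <- expand.grid(g = -3:3, B = (-3:3) * 0.15)
  dt <- 1 / bins_per_s
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    B <- grid$B[cell]
    g <- grid$g[cell]
    p <- model_params(nT = base$nT, s_t = base$s_t, s_h = base$s_h,
                      G = 1.2^g, B = B, stim_len = base$stim_len,
                      seed = base$seed + cell)
    sim <- lif_simulate(p, stimulus = stimulus)
    out <- data.frame(B = B, g = g, G = 1.2^g, spike_count = sim$spike_count,
                      latency_bins = NA_real_, latency_ms = NA_real_,
                      freq_hz = NA_real_, nl_slope = NA_real_)
    if (sim$spike_count >= min_spikes) {
      est <- sim_sta(stimulus, sim$spike_frames, base$nT)
      filt <- temporal_filter(est$sta, dt = dt, C = est$C)
      lat <- fit_dog_latency(filt, check_criterion = FALSE)
      out$latency_ms <- lat$latency_ms
      out$latency_bins <- lat$latency_ms / 1000 / dt
      # fine padding: the sweep compares small frequency shifts across cells,
      # so the spectral grid must be much denser than the shifts themselves
      out$freq_hz <- spectral_peak_frequency(filt, n_pad = 16384L)
      nl <- sim_nonlinearity(stimulus, sim$spike_frames, est$sta, dt = dt)
      out$nl_slope <- fit_halfwave_slope(nl)$slope
    }
    out
  })
  do.call(rbind, rows)
}

# Static nonlinearity of a frame-indexed simulation: projections of the lagged
# stimulus onto the L2-normalized STA, binned at 0.1.
sim_nonlinearity <- function(stimulus, spike_frames, sta, dt, bin = 0.1) {
  f <- sta / sqrt(sum(sta^2))
  proj <- as.numeric(stats::filter(stimulus, f, method = "convolution", sides = 1))
  valid <- which(!is.na(proj))
  counts <- integer(length(stimulus))
  counts[spike_frames] <- 1L
  bin_nonlinearity(proj[valid], counts[valid], dt = dt, bin = bin)
}

#' Fit a half-wave-rectified line to a static nonlinearity
#'
#' Least-squares fit of `rate = m * max(0, x - x0)` over occupied bins; the
#' slope summarizes the gain of the estimated nonlinearity.
#'
#' @param nl A [nonlinearity] object.
#' @param min_occupancy Bins with fewer stimulus frames are ignored.
#' @return List with `slope` (m >= 0), `threshold` (x0) and `ok` (FALSE when
#'   the fit degenerated to the all-zero solution).
#' @export
fit_halfwave_slope <- function(nl, min_occupancy = 1L) {
  stopifnot(inherits(nl, "nonlinearity"))
  keep <- nl$occupancy >= min_occupancy
  x <- nl$centers[keep]
  y <- nl$rate_hz[keep]
  if (length(x) < 3L) stop("need at least 3 occupied bins", call. = FALSE)
  if (all(y == 0)) {
    return(list(slope = 0, threshold = max(x), ok = FALSE))
  }
  w <- nl$occupancy[keep]
  sse <- function(par) {
    r <- y - pmax(0, par[1L]) * pmax(0, x - par[2L])
    sum(w * r^2)
  }
  # profile over x0 on the bin grid, slope has a closed form given x0
  best <- NULL
  for (x0 in x) {
    z <- pmax(0, x - x0)
    denom <- sum(w * z^2)
    m <- if (denom > 0) max(0, sum(w * y * z) / denom) else 0
    v <- sse(c(m, x0))
    if (is.null(best) || v < best$v) best <- list(m = m, x0 = x0, v = v)
  }
  fit <- optim(c(best$m, best$x0), sse, method = "Nelder-Mead")
  list(slope = max(0, fit$par[1L]), threshold = fit$par[2L], ok = TRUE)
}
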