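# Synthetic stimuli, ground-truth LN-Poisson neurons and behavior traces.
# These emulate the study conditions the estimators assume: binary full-field
# flicker at 60 FPS, constant-luminance 32x18 checkerboard noise, OFF-ON-OFF
# flashes (2 s epochs, 1 s gray inter-trial), 8-direction gratings, and
# pupil/locomotion/eye traces with controllable state structure.

#' Full-field white-noise stimulus
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fps Frame rate, default 60.
#' @param dist `"binary"` for equiprobable +-1 contrast steps, `"gaussian"`
#'   for standard-normal frames (used by the simulator).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param t0 Start time of the first frame, seconds.
#' @return A [stimulus_trace] of kind `fullfield`.
#' @export
gen_fullfield_noise <- function(duration_s, fps = 60, dist = c("binary", "gaussian"),
                                seed = 1L, t0 = 0) {
  dist <- match.arg(dist)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  n <- floor(duration_s * fps)
  values <- withr::with_seed(seed, {
    if (dist == "binary") sample(c(-1, 1), n, replace = TRUE) else rnorm(n)
  })
  stimulus_trace("fullfield", t0 + (seq_len(n) - 1L) / fps, values)
}

#' Constant-luminance checkerboard noise
#'
#' Each frame is a fresh random arrangement with exactly half the pixels white
#' (+1) and half black (-1), so the frame-mean luminance never varies.
#'
#' @inheritParams gen_fullfield_noise
#' @param ny,nx Grid rows and columns; `ny * nx` must be even.
#' @return A [stimulus_trace] of kind `checkerboard` with a frames x pixels
#'   value matrix.
#' @export
gen_checkerboard <- function(duration_s, fps = 60, ny = 18, nx = 32,
                             seed = 1L, t0 = 0) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  npx <- ny * nx
  if (npx %% 2L != 0L) stop("ny * nx must be even", call. = FALSE)
  n <- floor(duration_s * fps)
  values <- withr::with_seed(seed, {
    m <- matrix(-1, n, npx)
    for (i in seq_len(n)) {
      m[i, sample.int(npx, npx %/% 2L)] <- 1
    }
    m
  })
  stimulus_trace("checkerboard", t0 + (seq_len(n) - 1L) / fps, values,
                 ny = ny, nx = nx)
}

#' Full-field flash protocol (OFF-ON-OFF + gray inter-trial)
#'
#' Each trial is OFF (2 s), ON (2 s), OFF (2 s) at maximum contrast followed by
#' a 1 s gray inter-trial interval.
#'
#' @param n_trials Number of trials (>= 1).
#' @param epoch_s Duration of each OFF/ON/OFF epoch, seconds.
#' @param iti_s Gray inter-trial interval, seconds.
#' @param t0 Start time, seconds.
#' @return A [stimulus_trace] of kind `flash`; `frame_times` are epoch onsets
#'   and `values` the labels OFF/ON/OFF/GRAY per trial.
#' @export
gen_flash_protocol <- function(n_trials, epoch_s = 2, iti_s = 1, t0 = 0) {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  labels <- rep(c("OFF", "ON", "OFF", "GRAY"), n_trials)
  durs <- rep(c(epoch_s, epoch_s, epoch_s, iti_s), n_trials)
  onsets <- t0 + c(0, cumsum(durs)[-length(durs)])
  stimulus_trace("flash", onsets, labels)
}

#' Ground-truth LN neuron for synthetic sessions
#'
#' Defines a linear-nonlinear Poisson neuron: a unit-norm temporal filter, a
#' half-wave-rectified linear nonlinearity `rate = gain_state * max(0,
#' m * (projection - x0)) + baseline`, and optionally a 2-D Gaussian spatial
#' receptive field and a direction-tuning curve.
#'
#' @param true_filter Numeric temporal filter over lag bins (lag 0 = spike
#'   frame); L2-normalized internally.
#' @param nl_slope Rectified-linear slope `m`, Hz per unit projection (>= 0).
#' @param nl_threshold Projection threshold `x0`.
#' @param baseline_rate Additive baseline rate, Hz (>= 0).
#' @param state_gain Multiplicative factor applied to the rectified drive when
#'   the behavioral state flag is on (see [gen_ln_spikes()]).
#' @param spatial_rf Optional list `(cx, cy, sigma_long, sigma_short, theta)`
#'   in pixel units for checkerboard stimulation.
#' @param tuning Optional length-8 non-negative direction tuning curve, Hz.
#' @return An object of class `gt_neuron`.
#' @export
gt_neuron <- function(true_filter, nl_slope = 30, nl_threshold = 0.2,
                      baseline_rate = 1, state_gain = 1,
                      spatial_rf = NULL, tuning = NULL) {
  stopifnot(nl_slope >= 0, baseline_rate >= 0, state_gain >= 0)
  nrm <- sqrt(sum(true_filter^2))
  if (nrm == 0) stop("true_filter must be nonzero", call. = FALSE)
  if (!is.null(spatial_rf)) {
    stopifnot(spatial_rf$sigma_long >= spatial_rf$sigma_short,
              spatial_rf$sigma_short > 0)
  }
  if (!is.null(tuning)) stopifnot(length(tuning) == 8L, all(tuning >= 0))
  structure(
    list(true_filter = true_filter / nrm, nl_slope = nl_slope,
         nl_threshold = nl_threshold, baseline_rate = baseline_rate,
         state_gain = state_gain, spatial_rf = spatial_rf, tuning = tuning),
    class = "gt_neuron"
  )
}

#' Default biphasic ground-truth temporal filter
#'
#' A damped sine over `n_lags` frame bins resembling a fast OFF/ON biphasic
#' retinal filter; used throughout the synthetic fixtures.
#'
#' @param n_lags Filter length in frame bins.
#' @param peak_lag Lag (bins) of the main lobe.
#' @param polarity +1 for ON-dominant, -1 for OFF-dominant.
#' @return Unit-norm numeric vector of length `n_lags`.
#' @export
biphasic_filter <- function(n_lags = 30, peak_lag = 4, polarity = 1) {
  k <- seq_len(n_lags) - 1L
  f <- polarity * sin(pi * k / (2 * peak_lag)) * exp(-k / (1.6 * peak_lag))
  f / sqrt(sum(f^2))
}

# Gaussian RF weight map on the checkerboard grid, L2-normalized.
rf_weight_map <- function(rf, ny, nx) {
  gx <- rep(seq_len(nx), each = ny)
  gy <- rep(seq_len(ny), times = nx)
  dx <- gx - rf$cx
  dy <- gy - rf$cy
  th <- if (is.null(rf$theta)) 0 else rf$theta
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  w <- exp(-0.5 * (u / rf$sigma_long)^2 - 0.5 * (v / rf$sigma_short)^2)
  w / sqrt(sum(w^2))
}

# Causal projection of a stimulus onto a lag filter: p_i = sum_k f_k s_{i-k}.
# Frames with incomplete history get NA.
project_stimulus <- function(values, filt) {
  n_lags <- length(filt)
  p <- stats::filter(values, filt, method = "convolution", sides = 1)
  as.numeric(p)
}

#' Generate spikes from a ground-truth LN neuron
#'
#' Frame-clocked LN-Poisson generation: the stimulus is convolved with the
#' neuron's temporal filter (and weighted by its spatial receptive field for
#' checkerboard stimuli), passed through the rectified-linear nonlinearity, and
#' a Poisson spike count is drawn per frame at `rate * dt`. Spike times are
#' placed uniformly within their frame.
#'
#' @param stim A fullfield or checkerboard [stimulus_trace].
#' @param neuron A [gt_neuron].
#' @param state_on Optional per-frame logical; where `TRUE` the rectified drive
#'   is multiplied by `neuron$state_gain`.
#' @param seed Integer seed.
#' @param unit_id Unit label for the returned train.
#' @return A [spike_train] spanning the stimulus.
#' @export
gen_ln_spikes <- function(stim, neuron, state_on = NULL, seed = 1L,
                          unit_id = "gt") {
  stopifnot(inherits(stim, "stimulus_trace"), inherits(neuron, "gt_neuron"))
  if (!stim$kind %in% c("fullfield", "checkerboard")) {
    stop("gen_ln_spikes needs a fullfield or checkerboard stimulus", call. = FALSE)
  }
  n <- length(stim$frame_times)
  if (length(neuron$true_filter) > n) {
    stop("filter longer than stimulus", call. = FALSE)
  }
  drive_sig <- if (stim$kind == "fullfield") {
    stim$values
  } else {
    if (is.null(neuron$spatial_rf)) {
      stop("checkerboard stimulation requires a spatial_rf", call. = FALSE)
    }
    as.numeric(stim$values %*% rf_weight_map(neuron$spatial_rf, stim$ny, stim$nx))
  }
  proj <- project_stimulus(drive_sig, neuron$true_filter)
  proj[is.na(proj)] <- 0
  gain <- rep(1, n)
  if (!is.null(state_on)) {
    stopifnot(length(state_on) == n)
    gain[state_on] <- neuron$state_gain
  }
  rate <- gain * pmax(0, neuron$nl_slope * (proj - neuron$nl_threshold)) +
    neuron$baseline_rate
  dt <- median(diff(stim$frame_times))
  spikes <- withr::with_seed(seed, {
    counts <- rpois(n, rate * dt)
    idx <- rep.int(seq_len(n), counts)
    sort(stim$frame_times[idx] + runif(length(idx)) * dt)
  })
  spike_train(unit_id, spikes, stim$frame_times[1L],
              stim$frame_times[n] + dt)
}

#' Generate a behavior trace with controllable state structure
#'
#' Pupil size follows a slow mean-reverting (Ornstein-Uhlenbeck) walk so that
#' size tertiles and derivative states are all populated; locomotion is
#' generated as bouts from a two-state Markov chain calibrated to a target
#' running fraction; eye position is a sequence of jittered fixations with
#' occasional saccades.
#'
#' @param duration_s Trace duration, seconds (> 0).
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz (behavioral cameras run at 30-60 Hz).
#' @param pupil_tau_s Pupil autocorrelation time, seconds.
#' @param pupil_sd Stationary SD of the normalized pupil size.
#' @param run_fraction Target fraction of time spent running (0 disables
#'   locomotion entirely).
#' @param run_speed_cm_s Mean running speed during bouts, cm/s.
#' @param bout_s Mean running-bout duration, seconds.
#' @param saccade_rate_hz Rate of eye-position jumps, Hz.
#' @return A [behavior_trace].
#' @export
gen_behavior <- function(duration_s, seed = 1L, fs = 30,
                         pupil_tau_s = 20, pupil_sd = 0.15,
                         run_fraction = 0.3, run_speed_cm_s = 8,
                         bout_s = 5, saccade_rate_hz = 0.2) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  n <- floor(duration_s * fs)
  dt <- 1 / fs
  withr::with_seed(seed, {
    # Ornstein-Uhlenbeck pupil around 1 (median-normalized units).
    ar <- exp(-dt / pupil_tau_s)
    innov_sd <- pupil_sd * sqrt(1 - ar^2)
    pupil <- numeric(n)
    pupil[1L] <- 1 + rnorm(1L, sd = pupil_sd)
    for (i in 2:n) pupil[i] <- 1 + ar * (pupil[i - 1L] - 1) + rnorm(1L, sd = innov_sd)

    # Two-state Markov chain: mean bout bout_s, mean rest chosen so the
    # stationary running fraction equals run_fraction.
    speed <- numeric(n)
    if (run_fraction > 0) {
      p_stop <- dt / bout_s
      rest_s <- bout_s * (1 - run_fraction) / run_fraction
      p_go <- dt / rest_s
      running <- runif(1L) < run_fraction
      base <- rgamma(n, shape = 16, rate = 16 / run_speed_cm_s)
      for (i in seq_len(n)) {
        speed[i] <- if (running) base[i] else 0
        running <- if (running) runif(1L) >= p_stop else runif(1L) < p_go
      }
      # Light smoothing so bout edges ramp like a real treadmill signal.
      k <- pmax(1L, round(0.2 * fs))
      speed <- as.numeric(stats::filter(c(rep(0, k), speed), rep(1 / k, k),
                                        sides = 1))[-seq_len(k)]
      speed[is.na(speed)] <- 0
    }

    # Fixations with Poisson saccades and small jitter.
    n_sac <- rpois(1L, saccade_rate_hz * duration_s)
    sac_idx <- sort(sample.int(n, min(n_sac, n)))
    fix_x <- cumsum(c(rnorm(1L, sd = 2), rnorm(length(sac_idx), sd = 5)))
    fix_y <- cumsum(c(rnorm(1L, sd = 2), rnorm(length(sac_idx), sd = 5)))
    seg <- findInterval(seq_len(n), sac_idx) + 1L
    eye_x <- fix_x[seg] + rnorm(n, sd = 0.3)
    eye_y <- fix_y[seg] + rnorm(n, sd = 0.3)

    behavior_trace(seq_len(n) * dt - dt, pupil, speed, eye_x, eye_y)
  })
}

#' Simulate trial firing rates for 8-direction gratings
#'
#' @param neuron A [gt_neuron] with a `tuning` curve.
#' @param n_trials Trials per direction.
#' @param trial_s Trial duration used for the Poisson count, seconds.
#' @param seed Integer seed.
#' @return List with `directions_deg` (8 angles), `rates` (trials x 8 Hz
#'   matrix) and `mean_rates` (length 8).
#' @export
gen_grating_responses <- function(neuron, n_trials = 10, trial_s = 2, seed = 1L) {
  stopifnot(inherits(neuron, "gt_neuron"))
  if (is.null(neuron$tuning)) stop("neuron lacks a tuning curve", call. = FALSE)
  dirs <- seq(0, 315, by = 45)
  rates <- withr::with_seed(seed, {
    matrix(rpois(n_trials * 8L, rep(neuron$tuning * trial_s, each = n_trials)),
           n_trials, 8L) / trial_s
  })
  list(directions_deg = dirs, rates = rates, mean_rates = colMeans(rates))
}

#' Build a complete synthetic session
#'
#' Assembles full-field noise, checkerboard noise, a flash protocol and a
#' grating block plus a behavior trace, then draws LN-Poisson spikes for
#' `n_units` ground-truth neurons with staggered kinetics and polarities.
#'
#' @param n_units Number of ground-truth units.
#' @param seed Integer seed.
#' @param noise_s Duration of the full-field noise block, seconds.
#' @param checker_s Duration of the checkerboard block, seconds.
#' @param n_flash_trials Flash trials.
#' @param treatment,phase,animal_id Session metadata.
#' @return List with `session` (an [ln_session]) and `neurons` (the
#'   ground-truth [gt_neuron] list, for recovery checks).
#' @export
make_session <- function(n_units = 3, seed = 1L, noise_s = 300, checker_s = 300,
                         n_flash_trials = 10, treatment = "saline",
                         phase = "pre", animal_id = "synthetic") {
  ff <- gen_fullfield_noise(noise_s, seed = seed, t0 = 0)
  t_ck <- noise_s + 5
  ck <- gen_checkerboard(checker_s, seed = seed + 1L, t0 = t_ck)
  t_fl <- t_ck + checker_s + 5
  fl <- gen_flash_protocol(n_flash_trials, t0 = t_fl)
  t_gr <- max(fl$frame_times) + 2
  gr <- stimulus_trace("grating", t_gr + seq(0, by = 3, length.out = 8),
                       seq(0, 315, by = 45))
  t_end <- t_gr + 8 * 3 + 2

  neurons <- lapply(seq_len(n_units), function(i) {
    gt_neuron(
      biphasic_filter(peak_lag = 3 + i, polarity = if (i %% 2L) 1 else -1),
      nl_slope = 20 + 5 * i, nl_threshold = 0.2, baseline_rate = 1,
      spatial_rf = list(cx = 8 + 5 * i, cy = 6 + 2 * i,
                        sigma_long = 2, sigma_short = 1.5, theta = 0.3 * i),
      tuning = 5 + 4 * (1 + cos(seq(0, 2 * pi * 7 / 8, length.out = 8) -
                                  pi * (i - 1) / 2)))
  })
  units <- lapply(seq_len(n_units), function(i) {
    nrn <- neurons[[i]]
    s_ff <- gen_ln_spikes(ff, nrn, seed = seed + 10L * i)
    s_ck <- gen_ln_spikes(ck, nrn, seed = seed + 10L * i + 1L)
    spike_train(sprintf("unit_%02d", i),
                sort(c(s_ff$spike_times, s_ck$spike_times)), 0, t_end)
  })
  behavior <- gen_behavior(t_end, seed = seed + 99L)
  list(session = ln_session(units, list(ff, ck, fl, gr), behavior,
                            animal_id = animal_id, treatment = treatment,
                            phase = phase),
       neurons = neurons)
}
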