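# Independent brute-force oracles used to cross-check the vectorized
# estimators, plus small fixture builders shared across test files.

# Naive per-spike STA: loop over spikes, average the stimulus k frames back.
brute_sta <- function(spike_times, frame_times, values, n_lags,
                      state_mask = NULL) {
  dt <- median(diff(frame_times))
  sta <- numeric(n_lags)
  C <- 0L
  for (t in spike_times) {
    i <- findInterval(t, c(frame_times, frame_times[length(frame_times)] + dt))
    if (i < n_lags || i > length(frame_times)) next
    if (!is.null(state_mask) && !all(state_mask[(i - n_lags + 1L):i])) next
    for (k in 0:(n_lags - 1L)) sta[k + 1L] <- sta[k + 1L] + values[i - k]
    C <- C + 1L
  }
  list(sta = sta / C, C = C)
}

# One-line brute-force binner: count spikes with frame_i <= t < frame_{i+1}.
brute_bin <- function(spike_times, frame_times) {
  dt <- median(diff(frame_times))
  edges <- c(frame_times, frame_times[length(frame_times)] + dt)
  vapply(seq_along(frame_times), function(i) {
    sum(spike_times >= edges[i] & spike_times < edges[i + 1L])
  }, 0L)
}

# Homogeneous Poisson spike train over [0, dur].
poisson_train <- function(rate_hz, dur_s, seed, id = "poisson") {
  withr::with_seed(seed, {
    n <- rpois(1L, rate_hz * dur_s)
    spike_train(id, sort(runif(n, 0, dur_s)), 0, dur_s)
  })
}

# Behavior trace built directly from channel vectors at a fixed clock.
manual_behavior <- function(fs, pupil, speed = NULL, eye_x = NULL, eye_y = NULL) {
  n <- length(pupil)
  tt <- seq_len(n) / fs - 1 / fs
  z <- rep(0, n)
  behavior_trace(tt, pupil,
                 if (is.null(speed)) z else speed,
                 if (is.null(eye_x)) z else eye_x,
                 if (is.null(eye_y)) z else eye_y)
}
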