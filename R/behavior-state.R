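# Behavioral-state segmentation: per-frame masks from locomotion, pupil size,
# pupil derivative and eye position, used to condition the LN estimators.

# Nearest-sample alignment of a behavior channel onto the stimulus frame clock.
align_to_frames <- function(time, x, frame_times) {
  stopifnot(length(time) == length(x), length(time) >= 1L)
  idx <- findInterval(frame_times, time, all.inside = TRUE)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(time))
  nearer_hi <- (frame_times - time[lo]) > (time[hi] - frame_times)
  x[ifelse(nearer_hi, hi, lo)]
}

#' Locomotion state masks
#'
#' A frame counts as running when the treadmill speed (nearest behavior
#' sample) strictly exceeds `thr` (2 cm/s).
#'
#' @param behavior A [behavior_trace].
#' @param frame_times Stimulus frame clock, seconds.
#' @param thr Running threshold, cm/s.
#' @return List with logical masks `running`, `stationary`, and summaries
#'   `fraction_running` and `median_running_speed` (`NA` if never running).
#' @export
locomotion_mask <- function(behavior, frame_times, thr = 2) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (!length(frame_times)) stop("empty frame_times", call. = FALSE)
  speed <- align_to_frames(behavior$time, behavior$speed, frame_times)
  running <- speed > thr
  list(running = running, stationary = !running,
       fraction_running = mean(running),
       median_running_speed = if (any(running)) median(speed[running]) else NA_real_)
}

#' Pupil-size state masks (constricted / neutral / dilated)
#'
#' Splits the pupil-size distribution of the recording phase at its 33rd and
#' 66th percentiles; the three masks partition all frames.
#'
#' @inheritParams locomotion_mask
#' @return List with logical masks `constricted`, `neutral`, `dilated`,
#'   the `cuts` used, and `degenerate` (TRUE for a constant pupil, all frames
#'   neutral).
#' @export
pupil_size_states <- function(behavior, frame_times) {
  stopifnot(inherits(behavior, "behavior_trace"))
  pupil <- align_to_frames(behavior$time, behavior$pupil_size, frame_times)
  ok <- !is.na(pupil)
  if (length(unique(behavior$pupil_size[!is.na(behavior$pupil_size)])) < 3L) {
    warning("pupil trace is (near) constant: all frames classified neutral")
    return(list(constricted = rep(FALSE, length(pupil)),
                neutral = ok, dilated = rep(FALSE, length(pupil)),
                cuts = c(NA_real_, NA_real_), degenerate = TRUE))
  }
  cuts <- quantile(behavior$pupil_size, c(1 / 3, 2 / 3), na.rm = TRUE,
                   names = FALSE)
  constricted <- ok & pupil < cuts[1L]
  dilated <- ok & pupil > cuts[2L]
  neutral <- ok & !constricted & !dilated
  list(constricted = constricted, neutral = neutral, dilated = dilated,
       cuts = cuts, degenerate = FALSE)
}

#' Pupil-dynamics state masks (constricting / stable / dilating)
#'
#' Takes a centered finite-difference derivative of the (median-normalized)
#' pupil size, smooths it with a `smooth_s` boxcar, and thresholds at
#' `+-thr` (0.01 normalized point per second).
#'
#' @inheritParams locomotion_mask
#' @param thr Derivative threshold, points/s.
#' @param smooth_s Smoothing window, seconds.
#' @param normalize Divide by the trace median first (paper convention:
#'   pupil in units of the pre-treatment median). Default TRUE.
#' @return List with logical masks `constricting`, `stable`, `dilating`, and
#'   the per-frame `derivative`.
#' @export
pupil_derivative_states <- function(behavior, frame_times, thr = 0.01,
                                    smooth_s = 0.5, normalize = TRUE) {
  stopifnot(inherits(behavior, "behavior_trace"))
  t <- behavior$time
  p <- behavior$pupil_size
  if (normalize) p <- p / median(p, na.rm = TRUE)
  fs <- 1 / median(diff(t))
  if (length(t) < max(3L, round(smooth_s * fs))) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  n <- length(p)
  dp <- numeric(n)
  dp[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  dp[1L] <- dp[2L]
  dp[n] <- dp[n - 1L]
  k <- max(1L, round(smooth_s * fs))
  kernel <- rep(1 / k, k)
  sm <- as.numeric(stats::filter(c(rep(dp[1L], k), dp, rep(dp[n], k)),
                                 kernel, sides = 2L))[(k + 1L):(k + n)]
  d <- align_to_frames(t, sm, frame_times)
  list(constricting = d < -thr, stable = d >= -thr & d <= thr,
       dilating = d > thr, derivative = d)
}

#' Eye-position stability mask
#'
#' A behavior sample is "centered" when both eye coordinates lie within half
#' an inter-quartile range of their medians (a band of total width one IQR);
#' the mask keeps only centered runs lasting at least `min_dur_s` (2 s).
#' `rule = "quartiles"` instead keeps samples inside `[Q1, Q3]` per
#' coordinate.
#'
#' @inheritParams locomotion_mask
#' @param min_dur_s Minimum stable-run duration, seconds.
#' @param rule `"iqr_band"` (default) or `"quartiles"`.
#' @return Per-frame logical mask (possibly all-FALSE).
#' @export
eye_stability_mask <- function(behavior, frame_times, min_dur_s = 2,
                               rule = c("iqr_band", "quartiles")) {
  rule <- match.arg(rule)
  stopifnot(inherits(behavior, "behavior_trace"))
  centered_band <- function(x) {
    if (rule == "iqr_band") {
      iqr <- diff(quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE))
      abs(x - median(x, na.rm = TRUE)) <= iqr / 2
    } else {
      q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      x >= q[1L] & x <= q[2L]
    }
  }
  cen <- centered_band(behavior$eye_x) & centered_band(behavior$eye_y)
  cen[is.na(cen)] <- FALSE
  # prune runs shorter than min_dur_s on the behavior clock
  r <- rle(cen)
  t <- behavior$time
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && (t[ends[j]] - t[starts[j]]) < min_dur_s) {
      cen[starts[j]:ends[j]] <- FALSE
    }
  }
  as.logical(align_to_frames(t, cen, frame_times))
}
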