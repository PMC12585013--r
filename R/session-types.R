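#' lnkit: linear-nonlinear cascade analysis of state-conditioned spike trains
#'
#' Estimators for the linear-nonlinear (LN) cascade model of visual neurons
#' (spike-triggered averages, static nonlinearities, receptive-field fits),
#' behavioral-state segmentation of pupil/locomotion traces, an
#' integrate-and-fire Poisson simulator for gain/baseline sweeps, and the
#' paired/group statistics used to quantify treatment effects. A synthetic-data
#' module generates ground-truth LN-Poisson sessions so that the whole pipeline
#' is testable end to end.
#'
#' @importFrom stats approx convolve fft kmeans kruskal.test median optim
#'   p.adjust pnorm prcomp quantile rbinom rexp rgamma rnorm rpois runif sd var
#'   wilcox.test cor.test coef predict
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

FRAME_RATE <- 60
FRAME_DT <- 1 / FRAME_RATE

#' Spike train of a single unit
#'
#' @param unit_id Character scalar identifying the unit.
#' @param spike_times Numeric vector of spike times in seconds, non-decreasing.
#' @param t_start,t_end Recording span in seconds; all spikes must fall inside.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, t_start, t_end) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L)
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) {
    stop("spike_times of unit '", unit_id, "' are not sorted", call. = FALSE)
  }
  if (length(spike_times) &&
      (spike_times[1L] < t_start || spike_times[length(spike_times)] > t_end)) {
    stop("spike_times of unit '", unit_id, "' fall outside [t_start, t_end]",
         call. = FALSE)
  }
  structure(
    list(unit_id = unit_id, spike_times = spike_times,
         t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s': %d spikes on [%.3f, %.3f] s>\n",
              x$unit_id, length(x$spike_times), x$t_start, x$t_end))
  invisible(x)
}

STIM_KINDS <- c("fullfield", "checkerboard", "flash", "grating")

#' Frame-clocked stimulus trace
#'
#' Holds one visual stimulus segment. `values` depends on `kind`:
#' * `fullfield`: numeric per-frame scalar; binary contrast steps are +-1,
#'   Gaussian noise (for the simulator) is real-valued.
#' * `checkerboard`: numeric matrix, frames x (ny*nx) pixels, entries +-1, each
#'   frame with exactly half the pixels white (constant mean luminance).
#' * `flash`: character per-epoch label in OFF/ON/GRAY; `frame_times` are epoch
#'   onsets.
#' * `grating`: numeric per-block drift direction in degrees; `frame_times` are
#'   block onsets.
#'
#' @param kind One of `"fullfield"`, `"checkerboard"`, `"flash"`, `"grating"`.
#' @param frame_times Strictly increasing onset times, seconds.
#' @param values Per-frame values, see Details.
#' @param ny,nx Checkerboard grid size (rows, columns).
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(kind, frame_times, values, ny = NULL, nx = NULL) {
  kind <- match.arg(kind, STIM_KINDS)
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) < 1L || any(diff(frame_times) <= 0)) {
    stop("frame_times must be non-empty and strictly increasing", call. = FALSE)
  }
  n <- length(frame_times)
  if (kind == "checkerboard") {
    if (!is.matrix(values) || nrow(values) != n) {
      stop("checkerboard values must be a frames x pixels matrix", call. = FALSE)
    }
    if (is.null(ny) || is.null(nx) || ny * nx != ncol(values)) {
      stop("ny * nx must equal the pixel count", call. = FALSE)
    }
    if (!all(values %in% c(-1, 1))) {
      stop("checkerboard values must be +-1", call. = FALSE)
    }
    if (any(abs(rowSums(values)) > 0)) {
      stop("each checkerboard frame must have equal numbers of +1 and -1 pixels",
           call. = FALSE)
    }
  } else if (length(values) != n) {
    stop("values must have one entry per frame", call. = FALSE)
  }
  if (kind == "flash" && !all(values %in% c("OFF", "ON", "GRAY"))) {
    stop("flash labels must be OFF/ON/GRAY", call. = FALSE)
  }
  structure(
    list(kind = kind, frame_times = frame_times, values = values,
         ny = ny, nx = nx),
    class = "stimulus_trace"
  )
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace %s: %d frames, %.1f s>\n", x$kind,
              length(x$frame_times), diff(range(x$frame_times))))
  invisible(x)
}

#' Behavioral trace (pupil, locomotion, eye position)
#'
#' @param time Sample times, seconds, strictly increasing.
#' @param pupil_size Pupil large-axis diameter, arbitrary units (normalized by
#'   the pre-treatment median downstream).
#' @param speed Treadmill speed, cm/s, non-negative.
#' @param eye_x,eye_y Eye-position coordinates (camera pixels or degrees).
#' @return An object of class `behavior_trace`.
#' @export
behavior_trace <- function(time, pupil_size, speed, eye_x, eye_y) {
  time <- as.numeric(time)
  if (length(time) < 1L || any(diff(time) <= 0)) {
    stop("time must be non-empty and strictly increasing", call. = FALSE)
  }
  n <- length(time)
  chans <- list(pupil_size = pupil_size, speed = speed,
                eye_x = eye_x, eye_y = eye_y)
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n) {
      stop(nm, " must have the same length as time", call. = FALSE)
    }
  }
  if (any(speed < 0, na.rm = TRUE)) stop("speed must be >= 0", call. = FALSE)
  structure(
    c(list(time = time), lapply(chans, as.numeric)),
    class = "behavior_trace"
  )
}

TREATMENTS <- c("saline", "chlorphenamine", "ciproxifan", "psem_tmn",
                "psem_nontmn")

#' Recording session container
#'
#' Bundles spike trains, stimuli and behavior for one recording phase of one
#' animal.
#'
#' @param units List of [spike_train] objects.
#' @param stimuli List of [stimulus_trace] objects.
#' @param behavior A [behavior_trace] or `NULL`.
#' @param animal_id Character scalar.
#' @param treatment One of saline, chlorphenamine, ciproxifan, psem_tmn,
#'   psem_nontmn.
#' @param phase `"pre"` or `"post"` treatment.
#' @return An object of class `ln_session`.
#' @export
ln_session <- function(units, stimuli = list(), behavior = NULL,
                       animal_id = "synthetic", treatment = "saline",
                       phase = "pre") {
  stopifnot(is.list(units), is.list(stimuli))
  treatment <- match.arg(treatment, TREATMENTS)
  phase <- match.arg(phase, c("pre", "post"))
  for (u in units) stopifnot(inherits(u, "spike_train"))
  for (s in stimuli) stopifnot(inherits(s, "stimulus_trace"))
  if (!is.null(behavior)) stopifnot(inherits(behavior, "behavior_trace"))
  if (length(units)) {
    span <- range(unlist(lapply(units, function(u) c(u$t_start, u$t_end))))
    for (s in stimuli) {
      if (min(s$frame_times) < span[1L] || max(s$frame_times) > span[2L]) {
        stop("stimulus times fall outside the union of unit spans", call. = FALSE)
      }
    }
    if (!is.null(behavior) &&
        (min(behavior$time) < span[1L] || max(behavior$time) > span[2L])) {
      stop("behavior times fall outside the union of unit spans", call. = FALSE)
    }
  }
  structure(
    list(units = units, stimuli = stimuli, behavior = behavior,
         animal_id = animal_id, treatment = treatment, phase = phase),
    class = "ln_session"
  )
}

#' @export
print.ln_session <- function(x, ...) {
  cat(sprintf("<ln_session %s/%s/%s: %d units, %d stimuli, behavior: %s>\n",
              x$animal_id, x$treatment, x$phase, length(x$units),
              length(x$stimuli), if (is.null(x$behavior)) "none" else "yes"))
  invisible(x)
}
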