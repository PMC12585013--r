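# Reverse-correlation estimation of the LN cascade: temporal/spatial STAs with
# per-bin significance against the N(0, 1/C) null, the static nonlinearity
# P(response | stimulus) = N(stimulus | response) / N(stimulus) / dt, and the
# before/after gain ratio.

#' Temporal filter (STA) container
#'
#' @param values STA value per lag bin; lag 0 is the frame containing the
#'   spike, lag k the k-th frame before it.
#' @param dt Bin width, seconds (1/60 at the native frame rate).
#' @param C Number of spikes that entered the average.
#' @param p_values Optional per-bin p-values (see [sta_pvalues()]).
#' @return An object of class `temporal_filter`.
#' @export
temporal_filter <- function(values, dt = 1 / 60, C = 0L, p_values = NULL) {
  stopifnot(C >= 0, dt > 0)
  if (!is.null(p_values)) {
    stopifnot(length(p_values) == length(values), all(p_values >= 0 & p_values <= 1))
  }
  structure(list(values = as.numeric(values), dt = dt, n_lags = length(values),
                 C = as.integer(C), p_values = p_values),
            class = "temporal_filter")
}

#' @export
print.temporal_filter <- function(x, ...) {
  cat(sprintf("<temporal_filter: %d lags x %.4g s, C = %d spikes>\n",
              x$n_lags, x$dt, x$C))
  invisible(x)
}

# Frames whose full n_lags-deep stimulus history lies inside the mask (and the
# stimulus): used both for spike retention and for the nonlinearity ensemble.
frames_with_history <- function(n_frames, n_lags, state_mask = NULL) {
  ok <- rep(TRUE, n_frames)
  ok[seq_len(min(n_lags - 1L, n_frames))] <- FALSE
  if (!is.null(state_mask)) {
    stopifnot(length(state_mask) == n_frames)
    m <- as.logical(state_mask)
    m[is.na(m)] <- FALSE
    # frame kept iff it and all n_lags - 1 preceding frames are in-state
    run <- stats::filter(as.numeric(m), rep(1, n_lags), sides = 1)
    ok <- ok & !is.na(run) & run == n_lags
  }
  which(ok)
}

#' Spike-triggered average from a full-field noise stimulus
#'
#' `STA(k)` is the mean stimulus value `k` frames before each retained spike.
#' A spike is retained only when its frame and all `n_lags - 1` preceding
#' frames fall inside `state_mask` (clean state conditioning: histories that
#' straddle a state boundary are dropped).
#'
#' @param spikes A [spike_train].
#' @param stim A fullfield [stimulus_trace] (+-1 values).
#' @param state_mask Optional per-frame logical state mask.
#' @param n_lags Window length in frames; 30 frames = 500 ms at 60 FPS.
#' @param with_p Compute per-bin p-values (default TRUE).
#' @return A [temporal_filter] with `C` = retained spike count.
#' @export
compute_sta <- function(spikes, stim, state_mask = NULL, n_lags = 30L,
                        with_p = TRUE) {
  stopifnot(inherits(spikes, "spike_train"), inherits(stim, "stimulus_trace"))
  if (stim$kind != "fullfield") stop("compute_sta needs a fullfield stimulus",
                                     call. = FALSE)
  counts <- bin_spikes(spikes, stim$frame_times)
  keep <- frames_with_history(length(counts), n_lags, state_mask)
  keep <- keep[counts[keep] > 0L]
  C <- sum(counts[keep])
  if (C == 0L) stop("no spikes under mask", call. = FALSE)
  w <- counts[keep]
  sta <- vapply(0:(n_lags - 1L), function(k) {
    sum(w * stim$values[keep - k]) / C
  }, 0)
  filt <- temporal_filter(sta, dt = median(diff(stim$frame_times)), C = C)
  if (with_p) filt$p_values <- sta_pvalues(filt)
  filt
}

#' Per-bin STA significance
#'
#' Two-sided p-value per lag bin under the null that the STA bin is
#' N(0, 1/C) distributed (the exact null for a +-1 stimulus independent of
#' spiking): `p = 2 * (1 - Phi(|STA| * sqrt(C)))`.
#'
#' @param filter A [temporal_filter] with `C > 0`.
#' @return Numeric vector of p-values, one per lag bin.
#' @export
sta_pvalues <- function(filter) {
  stopifnot(inherits(filter, "temporal_filter"), filter$C > 0)
  2 * pnorm(abs(filter$values) * sqrt(filter$C), lower.tail = FALSE)
}

#' Does a filter pass the significance criterion?
#'
#' A unit's temporal filter is accepted when at least one lag bin within
#' `max_lag_s` of the spike reaches `p < p_thresh` (defaults: 200 ms, 1e-10).
#'
#' @param filter A [temporal_filter]; p-values are computed if absent.
#' @param max_lag_s Latest lag inspected, seconds.
#' @param p_thresh Significance threshold.
#' @return Logical scalar.
#' @export
passes_sta_criterion <- function(filter, max_lag_s = 0.2, p_thresh = 1e-10) {
  stopifnot(inherits(filter, "temporal_filter"))
  p <- filter$p_values
  if (is.null(p)) p <- sta_pvalues(filter)
  lags_s <- (seq_len(filter$n_lags) - 1L) * filter$dt
  any(p[lags_s <= max_lag_s] < p_thresh)
}

#' Static nonlinearity container
#'
#' Binned mapping from the filter-projected stimulus to firing rate,
#' `rate(bin) = N(stimulus | spike) / N(stimulus) / dt` in Hz.
#'
#' @param edges Bin edges over the projection axis.
#' @param rate_hz Firing rate per bin, Hz.
#' @param occupancy Stimulus-frame count per bin.
#' @param dt Frame duration, seconds.
#' @return An object of class `nonlinearity`.
#' @export
nonlinearity <- function(edges, rate_hz, occupancy, dt) {
  stopifnot(length(rate_hz) == length(edges) - 1L,
            length(occupancy) == length(rate_hz),
            all(rate_hz >= 0), all(occupancy >= 0))
  structure(list(edges = edges, centers = (edges[-1L] + edges[-length(edges)]) / 2,
                 rate_hz = rate_hz, occupancy = occupancy, dt = dt),
            class = "nonlinearity")
}

# Shared binning core: projections + per-frame spike counts -> nonlinearity.
bin_nonlinearity <- function(proj, counts, dt, bin = 0.1) {
  lo <- floor(min(proj) / bin) * bin
  hi <- ceiling(max(proj) / bin) * bin
  if (hi <= lo) hi <- lo + bin
  edges <- seq(lo, hi + bin / 2, by = bin)
  idx <- findInterval(proj, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  occ <- tabulate(idx, nbins = length(edges) - 1L)
  spk <- vapply(seq_len(length(edges) - 1L), function(b) {
    sum(counts[idx == b])
  }, 0)
  rate <- ifelse(occ > 0, spk / occ / dt, 0)
  nonlinearity(edges, rate, occ, dt)
}

#' Estimate the static nonlinearity
#'
#' Projects each frame's `n_lags`-deep stimulus history onto the L2-normalized
#' filter, then forms the histogram ratio
#' `rate(bin) = (spikes in bin) / (frames in bin) / dt` with bin width `bin`
#' (0.1 in units of the normalized projection).
#'
#' @inheritParams compute_sta
#' @param filter A [temporal_filter] (typically the unit's STA); must be
#'   nonzero.
#' @param bin Projection bin width.
#' @return A [nonlinearity].
#' @export
compute_nonlinearity <- function(spikes, stim, filter, state_mask = NULL,
                                 bin = 0.1) {
  stopifnot(inherits(filter, "temporal_filter"))
  if (stim$kind != "fullfield") stop("compute_nonlinearity needs a fullfield stimulus",
                                     call. = FALSE)
  nrm <- sqrt(sum(filter$values^2))
  if (nrm == 0) stop("zero-norm filter", call. = FALSE)
  f <- filter$values / nrm
  counts <- bin_spikes(spikes, stim$frame_times)
  proj <- as.numeric(stats::filter(stim$values, f, method = "convolution",
                                   sides = 1))
  keep <- frames_with_history(length(counts), filter$n_lags, state_mask)
  dt <- median(diff(stim$frame_times))
  bin_nonlinearity(proj[keep], counts[keep], dt = dt, bin = bin)
}

#' Response-gain change between two nonlinearities
#'
#' The gain ratio is the occupancy-weighted least-squares scalar `c`
#' minimizing `sum w * (after - c * before)^2` over bins occupied at least
#' `min_occupancy` times in both curves (`w` = the smaller of the two
#' occupancies). Returned as a percent change `100 * (c - 1)`; -50 means the
#' post-treatment curve is half the pre-treatment curve.
#'
#' @param nl_after,nl_before [nonlinearity] objects on the same bin grid.
#' @param min_occupancy Minimum occupancy per curve for a bin to count.
#' @param method `"ls"` (weighted least-squares scale, default) or
#'   `"median"` (median of per-bin after/before ratios).
#' @return Percent gain change (scalar), or `NA` (with a warning) when fewer
#'   than 3 common occupied bins exist.
#' @export
gain_ratio <- function(nl_after, nl_before, min_occupancy = 100L,
                       method = c("ls", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(nl_after, "nonlinearity"), inherits(nl_before, "nonlinearity"))
  # align by bin center (grids share the 0.1 lattice but may differ in span)
  ia <- match(round(nl_before$centers, 6), round(nl_after$centers, 6))
  ok <- which(!is.na(ia) & nl_before$occupancy >= min_occupancy &
                nl_after$occupancy[ia] >= min_occupancy)
  if (length(ok) < 3L) {
    warning("fewer than 3 common occupied bins; gain ratio undefined")
    return(NA_real_)
  }
  before <- nl_before$rate_hz[ok]
  after <- nl_after$rate_hz[ia[ok]]
  if (method == "ls") {
    w <- pmin(nl_before$occupancy[ok], nl_after$occupancy[ia[ok]])
    denom <- sum(w * before^2)
    if (denom == 0) {
      warning("pre-treatment curve is zero on all common bins")
      return(NA_real_)
    }
    c_hat <- sum(w * before * after) / denom
  } else {
    r <- after[before > 0] / before[before > 0]
    if (!length(r)) return(NA_real_)
    c_hat <- median(r)
  }
  100 * (c_hat - 1)
}

#' Spatial filter container
#'
#' @param map ny x nx spatial STA at the peak lag.
#' @param peak_lag Lag (frames) where the global-magnitude peak occurred.
#' @param C Retained spike count.
#' @param dt Frame duration, seconds.
#' @return An object of class `spatial_filter` (the Gaussian fit is added by
#'   [fit_rf()]).
#' @export
spatial_filter <- function(map, peak_lag, C, dt = 1 / 60) {
  stopifnot(is.matrix(map), C >= 0)
  structure(list(map = map, peak_lag = peak_lag, C = as.integer(C), dt = dt,
                 fit = NULL),
            class = "spatial_filter")
}

#' Spatial STA from checkerboard stimulation
#'
#' Computes the per-pixel temporal STA over `n_lags` frames, restricted to
#' eye-stable periods, and extracts the spatial map at the lag of the global
#' magnitude peak across pixels.
#'
#' @param spikes A [spike_train].
#' @param stim A checkerboard [stimulus_trace].
#' @param stable_mask Per-frame logical from [eye_stability_mask()] (or NULL
#'   to use all frames).
#' @param n_lags Temporal window, frames.
#' @return A [spatial_filter].
#' @export
compute_spatial_sta <- function(spikes, stim, stable_mask = NULL, n_lags = 30L) {
  stopifnot(inherits(spikes, "spike_train"), stim$kind == "checkerboard")
  counts <- bin_spikes(spikes, stim$frame_times)
  keep <- frames_with_history(length(counts), n_lags, stable_mask)
  keep <- keep[counts[keep] > 0L]
  C <- sum(counts[keep])
  if (C == 0L) stop("no spikes under mask", call. = FALSE)
  w <- counts[keep]
  sta_lags <- vapply(0:(n_lags - 1L), function(k) {
    colSums(stim$values[keep - k, , drop = FALSE] * w) / C
  }, numeric(ncol(stim$values)))
  peak <- which.max(apply(abs(sta_lags), 2L, max)) - 1L
  map <- matrix(sta_lags[, peak + 1L], stim$ny, stim$nx)
  spatial_filter(map, peak_lag = peak, C = C,
                 dt = median(diff(stim$frame_times)))
}
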