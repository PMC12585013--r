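# Scalar response descriptors derived from filters, flash responses, spatial
# maps and grating responses.

#' Peak latency by difference-of-Gaussians fit
#'
#' Fits `f(t) = A1 exp(-(t - mu1)^2 / 2 s1^2) - A2 exp(-(t - mu2)^2 / 2 s2^2)`
#' to the temporal filter by nonlinear least squares (initialized from the raw
#' argmax/argmin, up to 3 restarts) and reports the time of the
#' global-magnitude extremum of the fitted curve within the filter window.
#' Non-convergence falls back to the raw-extremum latency (flagged).
#'
#' @param filter A [temporal_filter].
#' @param check_criterion Refuse filters failing [passes_sta_criterion()]
#'   (default TRUE, as applied to recorded units).
#' @return List with `latency_ms`, `converged`, and the fitted `coefficients`
#'   (NULL on fallback).
#' @export
fit_dog_latency <- function(filter, check_criterion = TRUE) {
  stopifnot(inherits(filter, "temporal_filter"))
  if (check_criterion && !passes_sta_criterion(filter)) {
    stop("filter does not pass the significance criterion", call. = FALSE)
  }
  y <- filter$values
  t <- (seq_along(y) - 1L) * filter$dt
  window <- max(t)
  i_max <- which.max(y)
  i_min <- which.min(y)
  raw_latency <- t[if (abs(y[i_max]) >= abs(y[i_min])) i_max else i_min]

  starts <- list(
    c(A1 = max(y[i_max], 1e-3), mu1 = t[i_max], s1 = 2 * filter$dt,
      A2 = max(-y[i_min], 1e-3), mu2 = t[i_min], s2 = 2 * filter$dt),
    c(A1 = max(y[i_max], 1e-3), mu1 = t[i_max], s1 = 4 * filter$dt,
      A2 = max(-y[i_min], 1e-3), mu2 = t[i_min], s2 = 4 * filter$dt),
    c(A1 = max(abs(y)), mu1 = window / 4, s1 = window / 8,
      A2 = max(abs(y)) / 2, mu2 = window / 2, s2 = window / 8))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A1 * exp(-(t - mu1)^2 / (2 * s1^2)) -
          A2 * exp(-(t - mu2)^2 / (2 * s2^2)),
        data = data.frame(t = t, y = y), start = as.list(st),
        lower = c(0, 0, filter$dt / 2, 0, 0, filter$dt / 2),
        upper = c(Inf, window, window, Inf, window, window),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(list(latency_ms = 1000 * raw_latency, converged = FALSE,
                coefficients = NULL))
  }
  tt <- seq(0, window, length.out = 2000L)
  cf <- as.list(coef(fit))
  curve <- cf$A1 * exp(-(tt - cf$mu1)^2 / (2 * cf$s1^2)) -
    cf$A2 * exp(-(tt - cf$mu2)^2 / (2 * cf$s2^2))
  list(latency_ms = 1000 * tt[which.max(abs(curve))], converged = TRUE,
       coefficients = coef(fit))
}

#' Spectral peak frequency of a temporal filter
#'
#' Magnitude spectrum of the mean-subtracted filter, zero-padded to at least
#' `n_pad` samples; the peak is searched in the `band` (default 0.5-30 Hz,
#' inside the Nyquist limit of the 60 FPS frame clock).
#'
#' @param filter A [temporal_filter].
#' @param n_pad Minimum FFT length.
#' @param band Search band, Hz.
#' @return Peak frequency in Hz, or `NA` for a flat filter (with a warning).
#' @export
spectral_peak_frequency <- function(filter, n_pad = 1024L, band = c(0.5, 30)) {
  stopifnot(inherits(filter, "temporal_filter"))
  y <- filter$values - mean(filter$values)
  if (all(y == 0)) {
    warning("flat filter: spectral peak undefined")
    return(NA_real_)
  }
  n <- max(n_pad, length(y))
  spec <- Mod(fft(c(y, numeric(n - length(y)))))
  freq <- (seq_len(n) - 1L) / (n * filter$dt)
  hi <- min(band[2L], 1 / (2 * filter$dt))  # never search past Nyquist
  sel <- freq >= band[1L] & freq <= hi
  freq[sel][which.max(spec[sel])]
}

#' ON-OFF polarity index of a temporal filter
#'
#' `(P - V) / (P + V)` where `P` is the filter's peak (positive part maximum)
#' and `V` the magnitude of its valley; +1 for a purely positive (ON) filter,
#' -1 for purely negative (OFF), 0 for balanced biphasic.
#'
#' @param filter A [temporal_filter].
#' @return Value in `[-1, 1]`, or `NA` for the all-zero filter.
#' @export
polarity_index <- function(filter) {
  stopifnot(inherits(filter, "temporal_filter"))
  P <- max(c(filter$values, 0))
  V <- abs(min(c(filter$values, 0)))
  if (P + V == 0) return(NA_real_)
  (P - V) / (P + V)
}

#' Response signal-to-noise ratio across trials
#'
#' `SNR = var_t[<r(t)>_trials] / <var_trials[r(t)]>_t`: the temporal variance
#' of the trial-averaged response over the mean across-trial variance. Units
#' with `SNR > threshold` (0.15) count as robustly visually responsive. A
#' perfectly repeatable, time-varying response has zero denominator and
#' returns `Inf` (retained).
#'
#' @param trial_matrix trials x time matrix of firing rates (1/60 s bins over
#'   the ON-OFF response segment).
#' @param threshold Selection threshold on the ratio, default 0.15.
#' @return List with `snr` and `selected` (`snr > 0.15`).
#' @export
snr <- function(trial_matrix, threshold = 0.15) {
  stopifnot(is.matrix(trial_matrix), nrow(trial_matrix) >= 2L)
  num <- var(colMeans(trial_matrix))
  den <- mean(apply(trial_matrix, 2L, var))
  s <- if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
  list(snr = s, selected = s > threshold)
}

#' Flash (OFF-ON-OFF) response analysis
#'
#' Builds a trial-averaged PSTH at 1 ms resolution, smooths it with a Gaussian
#' kernel (support truncated at 6 SD), computes the ON-OFF index
#' `(r_ON - r_OFF2) / (r_ON + r_OFF2)` from the mean rates in the ON and
#' second-OFF epochs, and finds the response peak in the window `(0, 250]` ms
#' after stimulus onset (index >= 0) or offset (index < 0).
#'
#' @param spikes A [spike_train].
#' @param protocol A flash [stimulus_trace] from [gen_flash_protocol()].
#' @param smoothing_sd_ms Gaussian kernel SD, ms (the kernel's full support is
#'   6 SD). Default 2 ms.
#' @param search_ms Peak search window after the transition, ms.
#' @param peak_rule `"global"` (default) for the window's global maximum,
#'   `"first_local"` for the first local maximum.
#' @return List of class `flash_response`: `psth_hz` (1 ms bins over the 7 s
#'   trial), `on_off_index`, `peak_latency_ms`, `peak_rate_hz`, `n_trials`.
#' @export
flash_analysis <- function(spikes, protocol, smoothing_sd_ms = 2,
                           search_ms = 250, peak_rule = c("global", "first_local")) {
  peak_rule <- match.arg(peak_rule)
  stopifnot(inherits(spikes, "spike_train"), protocol$kind == "flash")
  lab <- protocol$values
  trial_starts <- protocol$frame_times[seq(1L, length(lab), by = 4L)]
  n_trials <- length(trial_starts)
  if (n_trials < 2L) stop("need at least 2 trials", call. = FALSE)
  epoch_s <- protocol$frame_times[2L] - protocol$frame_times[1L]
  trial_s <- 3 * epoch_s
  n_bins <- round(trial_s * 1000)

  counts <- numeric(n_bins)
  for (ts in trial_starts) {
    rel <- spikes$spike_times - ts
    rel <- rel[rel >= 0 & rel < trial_s]
    if (length(rel)) {
      counts <- counts + tabulate(floor(rel * 1000) + 1L, nbins = n_bins)
    }
  }
  psth <- counts / n_trials * 1000  # Hz

  sd_bins <- smoothing_sd_ms  # 1 ms bins
  half <- max(1L, round(3 * sd_bins))
  kk <- exp(-0.5 * ((-half:half) / sd_bins)^2)
  kk <- kk / sum(kk)
  sm <- as.numeric(stats::filter(c(rep(psth[1L], half), psth,
                                   rep(psth[n_bins], half)), kk, sides = 2L))
  sm <- sm[(half + 1L):(half + n_bins)]

  on_win <- seq(round(epoch_s * 1000) + 1L, round(2 * epoch_s * 1000))
  off2_win <- seq(round(2 * epoch_s * 1000) + 1L, n_bins)
  r_on <- mean(psth[on_win])
  r_off <- mean(psth[off2_win])
  onoff <- if (r_on + r_off == 0) NA_real_ else (r_on - r_off) / (r_on + r_off)

  anchor_ms <- if (!is.na(onoff) && onoff >= 0) epoch_s * 1000 else 2 * epoch_s * 1000
  win <- seq(round(anchor_ms) + 1L, min(n_bins, round(anchor_ms + search_ms)))
  peak_latency <- NA_real_
  peak_rate <- NA_real_
  if (sum(counts[win]) > 0) {
    seg <- sm[win]
    i_pk <- if (peak_rule == "global") {
      which.max(seg)
    } else {
      loc <- which(diff(sign(diff(seg))) < 0) + 1L
      if (length(loc)) loc[1L] else which.max(seg)
    }
    peak_latency <- win[i_pk] - anchor_ms - 0.5
    peak_rate <- seg[i_pk]
  }
  structure(list(psth_hz = sm, on_off_index = onoff,
                 peak_latency_ms = peak_latency, peak_rate_hz = peak_rate,
                 n_trials = n_trials),
            class = "flash_response")
}

#' Fit a 2-D Gaussian receptive field
#'
#' Fits amplitude, center, axis SDs, orientation and offset to a spatial STA
#' map by least squares, and reports the receptive-field size as twice the
#' mean SD of the long and short axes, `2 * (sigma_long + sigma_short) / 2 =
#' sigma_long + sigma_short` (pixels).
#'
#' @param spatial A [spatial_filter].
#' @return The input with `$fit` set: list `(amp, cx, cy, sigma_long,
#'   sigma_short, theta, offset, rf_size, converged)`.
#' @export
fit_rf <- function(spatial) {
  stopifnot(inherits(spatial, "spatial_filter"))
  map <- spatial$map
  ny <- nrow(map)
  nx <- ncol(map)
  gx <- rep(seq_len(nx), each = ny)
  gy <- rep(seq_len(ny), times = nx)
  z <- as.numeric(map)
  sgn <- if (abs(max(z)) >= abs(min(z))) 1 else -1
  zp <- sgn * z
  i0 <- which.max(zp)
  par0 <- c(amp = max(zp) - median(zp), cx = gx[i0], cy = gy[i0],
            lsl = log(2), lss = log(1.5), theta = 0, off = median(zp))
  model <- function(p) {
    sl <- exp(p[4L]); ss <- exp(p[5L])
    u <- cos(p[6L]) * (gx - p[2L]) + sin(p[6L]) * (gy - p[3L])
    v <- -sin(p[6L]) * (gx - p[2L]) + cos(p[6L]) * (gy - p[3L])
    p[1L] * exp(-0.5 * (u / sl)^2 - 0.5 * (v / ss)^2) + p[7L]
  }
  obj <- function(p) sum((zp - model(p))^2)
  fit <- tryCatch(optim(par0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    spatial$fit <- list(converged = FALSE, rf_size = NA_real_)
    return(spatial)
  }
  p <- fit$par
  s1 <- exp(p[4L]); s2 <- exp(p[5L])
  sigma_long <- max(s1, s2)
  sigma_short <- min(s1, s2)
  theta <- if (s1 >= s2) p[6L] else p[6L] + pi / 2
  theta <- atan2(sin(theta), cos(theta))
  spatial$fit <- list(amp = sgn * p[1L], cx = unname(p[2L]), cy = unname(p[3L]),
                      sigma_long = sigma_long, sigma_short = sigma_short,
                      theta = theta, offset = sgn * p[7L],
                      rf_size = sigma_long + sigma_short,
                      converged = fit$convergence == 0L)
  spatial
}

#' Direction / orientation selectivity index
#'
#' Projects the per-direction mean rates onto a complex exponential:
#' `||sum_k r_k exp(-i a w_k)|| / sum_k r_k` with `a = 1` for direction
#' selectivity and `a = 2` for orientation selectivity.
#'
#' @param rates Non-negative mean rates, one per direction.
#' @param directions_deg Stimulus directions in degrees (default 8 equispaced).
#' @param alpha 1 (DS) or 2 (OS).
#' @return Index in `[0, 1]`; `NA` if all rates are zero.
#' @export
ds_os_index <- function(rates, directions_deg = seq(0, 315, by = 45),
                        alpha = 1) {
  stopifnot(length(rates) == length(directions_deg), all(rates >= 0),
            alpha %in% c(1, 2))
  tot <- sum(rates)
  if (tot == 0) return(NA_real_)
  w <- directions_deg * pi / 180
  Mod(sum(rates * exp(-1i * alpha * w))) / tot
}

#' Cluster temporal filters into six functional types
#'
#' L2-normalizes the filters, embeds them in two dimensions by principal
#' components, and partitions them with K-means (K-means++ seeding, run under
#' the given seed so labels are deterministic). Clusters are then named
#' `fast/plain/slow x ON/OFF` from the majority polarity of each cluster mean
#' and the latency terciles within each polarity.
#'
#' @param filters List of equal-length [temporal_filter] objects (>= k).
#' @param k Number of clusters, default 6.
#' @param seed Integer seed.
#' @return List with `labels` (integer cluster per filter), `type` (character
#'   names), `centers`, `embedding` (n x 2), and `degenerate` (TRUE when the
#'   inputs had no variance to cluster).
#' @export
classify_types <- function(filters, k = 6L, seed = 1L) {
  stopifnot(length(filters) >= k)
  X <- t(vapply(filters, function(f) {
    v <- f$values
    v / sqrt(sum(v^2))
  }, numeric(filters[[1L]]$n_lags)))
  if (all(apply(X, 2L, function(col) length(unique(col)) == 1L))) {
    warning("all filters identical: degenerate clustering")
    return(list(labels = rep(1L, nrow(X)), type = rep("degenerate", nrow(X)),
                centers = NULL, embedding = NULL, degenerate = TRUE))
  }
  emb <- prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  km <- withr::with_seed(seed, {
    centers <- kmeanspp_init(emb, k)
    kmeans(emb, centers = centers, iter.max = 100L)
  })
  labels <- km$cluster

  # name clusters: polarity sign of cluster-mean filter, latency terciles
  info <- lapply(seq_len(k), function(cl) {
    m <- colMeans(X[labels == cl, , drop = FALSE])
    pol <- if (abs(max(m)) >= abs(min(m))) "ON" else "OFF"
    lat <- which.max(abs(m))
    list(pol = pol, lat = lat)
  })
  type_names <- character(k)
  for (pol in c("ON", "OFF")) {
    idx <- which(vapply(info, `[[`, "", "pol") == pol)
    if (!length(idx)) next
    lats <- vapply(info[idx], `[[`, 0L, "lat")
    speed <- c("fast", "", "slow")[findInterval(rank(lats, ties.method = "first"),
                                                c(1, length(idx) / 3 + 1,
                                                  2 * length(idx) / 3 + 1))]
    type_names[idx] <- trimws(paste(speed, pol))
  }
  list(labels = labels, type = type_names[labels], centers = km$centers,
       embedding = emb, degenerate = FALSE)
}

# K-means++ seeding: first center uniform, then D^2-weighted.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
    dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}
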