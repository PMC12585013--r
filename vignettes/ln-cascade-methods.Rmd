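---
title: "Methods: LN-cascade estimation, state conditioning and the gain/baseline model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LN-cascade estimation, state conditioning and the gain/baseline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnkit)
```

This vignette documents the models, conventions and numerical choices
behind `lnkit`. It is the package's reference for *why* each estimator is
built the way it is; the README shows *how* to run them.

## The LN model and its estimators

A visual neuron is modeled as a linear–nonlinear–Poisson (LN) cascade: a
temporal filter applied to the frame-clocked stimulus, a static
nonlinearity mapping the filtered value to a firing rate, and Poisson
spike generation. The estimators are the classical reverse-correlation
pair:

* **Temporal filter.** The spike-triggered average (STA) over 30 lag
  bins of 1/60 s (a 500 ms window). Lag 0 is the frame *containing* the
  spike and lag k the k-th frame before it; this convention is stated
  explicitly because nothing in the mathematics forces it, and every
  downstream latency is measured on this axis. For a ±1 stimulus
  independent of spiking, each STA bin is asymptotically N(0, 1/C) with
  C the spike count, which gives exact per-bin p-values and the
  unit-selection rule (p < 1e-10 in some bin within 200 ms). The
  threshold is deliberately extreme: with ~13 bins inspected per unit
  and hundreds of units, a lenient cut would admit stimulus-independent
  units at a non-negligible rate, while a true filter at realistic spike
  counts reaches p values many orders of magnitude smaller.

* **Static nonlinearity.** The histogram-ratio estimator
  `rate(x) = N(x | spike) / N(x) / dt` over projections `x` of the
  stimulus history onto the L2-normalized STA, bin width 0.1. Because
  the same frames enter numerator and denominator, the estimator
  conserves spikes exactly: `sum(rate * occupancy * dt)` equals the
  retained spike count, which the tests assert to machine precision.
  The projection axis uses each phase's own STA (pre or post); a shared
  axis would misattribute filter changes to gain changes when the
  filter itself moves. This choice matters only in the before/after
  comparison and is configurable by passing whichever filter is wanted.

* **Gain ratio.** The before/after comparison reduces two curves to one
  scalar: the occupancy-weighted least-squares scale `c` minimizing
  `sum w (after - c * before)^2` over bins with occupancy >= 100 in both
  phases, reported as `100 (c - 1)` percent. A per-bin median ratio is
  available (`method = "median"`); the weighted scale is the default
  because it down-weights sparse tail bins where the ratio estimate is
  dominated by Poisson noise.

State conditioning drops any spike whose full 500 ms stimulus history is
not inside the state mask. Zero-padding the history instead would mix
states across the boundary — precisely what state-conditioned estimation
is meant to prevent — at the cost of discarding a 30-frame margin at
every state transition.

## Scalar response descriptors

* **Peak latency** comes from a difference-of-Gaussians fit to the
  temporal filter (nonlinear least squares, initialized at the raw
  argmax/argmin, three restarts, means constrained to the window and SDs
  to [dt/2, window]). The latency is the global-magnitude extremum of
  the *fitted* curve on a fine grid, which interpolates below the bin
  width; non-convergence falls back to the raw extremum and is flagged.
* **Spectral peak frequency** is the argmax of the magnitude spectrum of
  the mean-subtracted filter, zero-padded to >= 1024 samples, searched
  in 0.5–30 Hz and never past the Nyquist frequency of the filter's own
  sampling. The sweep uses a 16384-point pad because it compares
  frequency shifts far smaller than the 1024-point grid step.
* **ON–OFF polarity** `(P - V)/(P + V)` from the filter's peak and
  valley magnitudes; **flash responses** use a 1 ms PSTH smoothed by a
  Gaussian kernel truncated at 6 SD. The kernel SD is a free parameter
  (default 2 ms) since trial counts in this preparation are small and
  the optimal bandwidth is response-dependent. The peak is the global
  maximum within 250 ms after onset (ON-dominated units) or offset
  (OFF-dominated); a first-local-maximum rule is available, and the two
  differ only for multi-peaked responses.
* **SNR** is `var_t[trial mean] / mean_t[trial variance]` on 1/60 s
  bins; identical trials give an infinite ratio and are retained, since
  perfect repeatability is the strongest possible visual response.
* **RF size** is `sigma_long + sigma_short` (twice the mean axis SD) of
  a rotated 2-D Gaussian fit by BFGS on the spatial STA at its global
  peak lag, with log-parameterized SDs to keep them positive. For
  isotropic fields the orientation is unidentifiable but the size —
  the only quantity consumed downstream — is stable.
* **Functional typing** embeds L2-normalized filters in two principal
  components and clusters with K-means seeded by the K-means++ rule
  under a caller seed, then names the six clusters fast/–/slow × ON/OFF
  by cluster-mean polarity and latency terciles. A deterministic linear
  embedding was chosen over stochastic neighbor embeddings so that
  labels are exactly reproducible; for curves as smooth as 30-bin
  temporal filters, two principal components already separate polarity
  and kinetics, which is all the naming heuristic needs.

## Behavioral-state segmentation

Thresholds follow the field's conventions: running at speed > 2 cm/s;
pupil-size tertiles at the 33rd/66th percentiles of the recording phase;
pupil-derivative states at ±0.01 normalized point/s on a centered
difference smoothed over 0.5 s (the smoothing window is ours — an
unsmoothed derivative of a 30 Hz trace is dominated by sample noise at
this threshold); eye stability as both coordinates within *half an IQR
of the median* (a band of total width one IQR) sustained for >= 2 s.
The bracketed reading `[Q1, Q3]` of "within one IQR" is defensible too
and is available via `rule = "quartiles"`; the centered band is the
default because it is symmetric around the resting position. Behavior
channels are aligned to the frame clock by nearest sample, adequate for
traces sampled at 30–60 Hz against a 60 FPS clock.

## The synthetic-data generator

The generator produces exactly the stimulus battery the estimators
assume: binary full-field flicker at 60 FPS; 32 × 18 checkerboard noise
with exactly half the pixels white per frame (constant mean luminance —
note this makes pixels weakly anti-correlated, −1/575, which the tests
account for); OFF–ON–OFF flashes of 2 s epochs with 1 s gray intervals;
eight-direction gratings summarized at the trial-rate level. Ground-truth
neurons are LN-Poisson: unit-norm filter, rate
`g_state * max(0, m (x - x0)) + baseline`, Poisson counts per frame with
spike times uniform within the frame. The state gain multiplies the
rectified drive, not the baseline, so gain-type and baseline-type
modulations can be emulated independently when probing the model
analysis.

Behavior is emulated at the level the segmentation consumes: pupil as an
Ornstein–Uhlenbeck walk (tau = 20 s, stationary SD 0.15 around a
normalized mean of 1) so tertiles and derivative states are all
populated; locomotion as a two-state Markov chain (mean bout 5 s, rest
duration set by the target duty cycle, gamma-distributed speeds around
8 cm/s, lightly smoothed); eye position as jittered fixations with
Poisson saccades. These are *statistical* stand-ins: they have the
right thresholds, autocorrelation times and occupancies, but none of
the kinematic fine structure of real pupillometry or treadmill data, so
passing tests certify the segmentation logic, not biological realism.
Real sessions also couple behavior to neural gain in ways the generator
only emulates when explicitly told to (`state_on`).

## The integrate-and-fire model

The model neuron's filter is a single sine cycle on a log-warped time
axis (`nT = 25`, `s_t = 1.5`), its drive is
`V(i) = G (sum_j L(j) S(i-j) + B)` on Gaussian white noise normalized to
maximum absolute value 1, and spiking is a fresh uniform(0,1) threshold
per bin with additive refractory kernels `-exp(-j / s_h)`, `j = 0..5`.
Numerical conventions that the source description leaves open, fixed
here once:

* The comparison is strict (`V > u`), so `G·B > 1` guarantees spiking
  and a non-positive drive guarantees silence.
* The refractory kernel starts at the first bin *after* the spike.
  Applying `-1` at the spike bin itself cannot retract an
  already-decided spike in a causal loop; in our implementation an
  offset-0 kernel simply wastes its strongest tap (a sensitivity flag
  `refractory_offset = 0` exposes this, and the tests show it weakens
  suppression). Overlapping kernels from bursts sum linearly.
* The first `nT - 1` bins have incomplete stimulus history and never
  spike.
* The sweep reuses one stimulus realization across all 49 cells —
  matching the single-stimulus design of the analysis it supports — and
  draws each cell's thresholds from `base seed + cell index`, so cells
  are independent in their stochastic component but share drive.

Sweep features are estimated exactly as for recorded units (STA over
`nT` lags, DoG latency, spectral peak, half-wave slope); cells with
fewer than 100 spikes get `NA` features rather than errors, since the
low-gain/low-baseline corner of the grid can be nearly silent. The
half-wave slope fit profiles the threshold over the occupied bins (the
slope has a closed form given the threshold) before a Nelder–Mead
polish; this avoids the local minima a joint fit hits when most bins are
sub-threshold.

## Problem sizes and tolerances

The test and acceptance runs use the study's native scales where they
matter and scaled-down sizes where only correctness is at stake: the
full 49-cell sweep runs on 10^6 frames (about half a minute), filter
recovery uses 15 min of 60 FPS noise (cosine > 0.9 asserted; observed
~0.999), slope recovery 10% on bins with occupancy >= 200, the imposed
−50% gain change must read out in [−60, −40]% on every one of 20
replicate sessions of 5 min per phase, null calibration uses 100
stimulus-independent units (≥ 99 must fail the selection criterion) and
1000 Kruskal–Wallis replicates (size within [3, 7]% at alpha = 0.05).
Unit tests that only exercise logic run at much smaller sizes.

## Known limitations

* The estimators assume frame-locked analysis throughout; spike timing
  within a frame is discarded, as in the analyses this package
  reimplements.
* No regularized RF estimation (ridge/GLM): white-noise stimuli make
  the plain STA unbiased, and that is the estimator being studied.
* The Dunn-style post-hoc on average group ranks is one defensible
  reading of "post-hoc test on the average group ranks"; it is
  implemented by hand with tie correction and Holm adjustment, and the
  adjustment is configurable.
* `load_session`/`save_session` use a versioned plain-text directory
  format (CSV tables + JSON metadata). It is transparent and
  byte-stable, but not a hierarchical binary container; sessions much
  longer than an hour of checkerboard stimulation will be slow to read.
* Dropped frames are handled by trusting recorded frame times
  (`frame_times` are authoritative; the nominal 60 FPS is only a
  default), and the binning convention is half-open `[frame, next)`
  with boundary spikes assigned to the later bin.
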