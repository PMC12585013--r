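#!/usr/bin/env Rscript
# Behavioral-state conditioning: generates a session in which a unit's
# response gain depends on a designated behavioral state (running), then
# shows that state-conditioned STAs and nonlinearities separate the two
# states while the state masks themselves recover the generator's structure.
#
# Writes: results/state_masks.csv, results/state_conditioned_gain.csv

library(lnkit)

dur <- 600
beh <- gen_behavior(dur, seed = 21L, run_fraction = 0.3)
stim <- gen_fullfield_noise(dur, seed = 22L)
frames <- stim$frame_times

loco <- locomotion_mask(beh, frames)
ps <- pupil_size_states(beh, frames)
pd <- pupil_derivative_states(beh, frames)
eye <- eye_stability_mask(beh, frames)

masks <- data.frame(
  mask = c("running", "stationary", "pupil constricted", "pupil neutral",
           "pupil dilated", "constricting", "stable", "dilating", "eye stable"),
  fraction = c(mean(loco$running), mean(loco$stationary), mean(ps$constricted),
               mean(ps$neutral), mean(ps$dilated), mean(pd$constricting),
               mean(pd$stable), mean(pd$dilating), mean(eye)))
write.csv(masks, "results/state_masks.csv", row.names = FALSE)
cat("State-mask coverage:\n")
print(masks, row.names = FALSE, digits = 3)
cat("Fraction running:", round(loco$fraction_running, 3),
    "| median running speed:", round(loco$median_running_speed, 2), "cm/s\n\n")

# unit whose rectified drive doubles while running
nrn <- gt_neuron(biphasic_filter(), nl_slope = 30, nl_threshold = 0.1,
                 baseline_rate = 2, state_gain = 2)
spk <- gen_ln_spikes(stim, nrn, state_on = loco$running, seed = 23L)

sta_run <- compute_sta(spk, stim, state_mask = loco$running)
sta_stat <- compute_sta(spk, stim, state_mask = loco$stationary)
nl_run <- compute_nonlinearity(spk, stim, sta_run, state_mask = loco$running)
nl_stat <- compute_nonlinearity(spk, stim, sta_stat,
                                state_mask = loco$stationary)
g <- gain_ratio(nl_run, nl_stat, min_occupancy = 50L)

out <- data.frame(state = c("running", "stationary"),
                  retained_spikes = c(sta_run$C, sta_stat$C),
                  gain_vs_stationary_pct = c(g, 0))
write.csv(out, "results/state_conditioned_gain.csv", row.names = FALSE)
cat("State-conditioned gain (running vs stationary):", round(g, 1),
    "% (ground truth: +100% on the rectified drive)\n")
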