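#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study sessions every later stage consumes.
#
# Three session types, all deterministic under SEED:
#   * a sensory-evoked session (40 visual stimuli, 10-s ISI, strobed 80 Hz),
#   * a natural-sleep session (wake/NREM/REM blocks, strobed, with 2-kHz
#     EMG/LFP and five motion-energy traces),
#   * pre/post GAT-1-blocker ROI traces with spontaneous transients
#     (rate and amplitude doubled post-injection).
# Raw inputs are written under results/data/ in the interchange formats
# (float32 TIFF + JSON sidecar, CSV traces) so stages 2-6 can be run from
# files alone.

suppressPackageStartupMessages(library(mesogaba))
SEED <- 20260101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating evoked session (32x32, 410 s, 40 trials) ...")
cfg_ev <- evoked_scenario(image_shape = c(32, 32),
                          rng_seed = split_seed(SEED, "simulate"))
sim_ev <- simulate_movie(cfg_ev)
write_movie(sim_ev$movie, file.path(out, "evoked_movie.tif"))
write_stim_csv(sim_ev$truth$stim_times, file.path(out, "evoked_stim.csv"))
saveRDS(cfg_ev, file.path(out, "evoked_config.rds"))

message("simulating sleep session (32x32, 300 s, W/N/R blocks) ...")
cfg_sl <- sleep_scenario(image_shape = c(32, 32),
                         rng_seed = split_seed(SEED, "simulate") + 1)
sim_sl <- simulate_movie(cfg_sl)
eph <- simulate_ephys(cfg_sl$state_block_spec, cfg_sl)
write_movie(sim_sl$movie, file.path(out, "sleep_movie.tif"))
write_analog_csv(eph$emg, eph$rate, file.path(out, "sleep_emg.csv"), "emg")
write_analog_csv(eph$lfp, eph$rate, file.path(out, "sleep_lfp.csv"), "lfp")
for (j in seq_len(ncol(eph$motion)))
  write_analog_csv(eph$motion[, j], eph$rate,
                   file.path(out, sprintf("sleep_motion_%d.csv", j)),
                   "motion_roi")
saveRDS(list(config = cfg_sl, truth = sim_sl$truth[
  c("state_blocks", "stim_times")], motion_periods = eph$motion_periods),
  file.path(out, "sleep_truth.rds"))

message("simulating pre/post drug ROI traces (6 subjects) ...")
drug <- lapply(1:6, function(i) list(
  pre = simulate_transient_trace(300, 40, n_events = NULL, rate_per_min = 3,
                                 amplitude = 0.04, noise_sd = 0.01,
                                 seed = split_seed(SEED, "transients") + i),
  post = simulate_transient_trace(300, 40, n_events = NULL, rate_per_min = 6,
                                  amplitude = 0.08, noise_sd = 0.01,
                                  seed = split_seed(SEED, "transients") +
                                    500 + i)))
for (i in seq_along(drug)) {
  write_analog_csv(drug[[i]]$pre$trace, 40,
                   file.path(out, sprintf("drug_pre_%d.csv", i)), "roi")
  write_analog_csv(drug[[i]]$post$trace, 40,
                   file.path(out, sprintf("drug_post_%d.csv", i)), "roi")
}

message("done; inputs under ", out)
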