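#!/usr/bin/env Rscript
# Stage 4 — motion exclusion and vigilance-state scoring of the sleep
# session: robust EMG power envelope, 95th-percentile movement intervals,
# per-epoch EMG power / theta-delta ratio / composite motion z, rule-based
# WAKE/NREM/REM labels, accuracy against the generator's hypnogram.

suppressPackageStartupMessages(library(mesogaba))

emg <- read_analog_csv("results/data/sleep_emg.csv")
lfp <- read_analog_csv("results/data/sleep_lfp.csv")
motion <- sapply(1:5, function(j)
  read_analog_csv(sprintf("results/data/sleep_motion_%d.csv", j))$trace)
truth <- readRDS("results/data/sleep_truth.rds")
rate <- emg$rate

pe <- process_emg(emg$trace, rate)
mp <- detect_motion_periods(pe, rate)
write.csv(mp$intervals, "results/tables/motion_periods.csv",
          row.names = FALSE)
message(sprintf("detected %d movement periods (%.1f s total)",
                nrow(mp$intervals),
                sum(mp$intervals$offset - mp$intervals$onset)))

fe <- epoch_features(emg$trace, lfp$trace, motion, rate, epoch_s = 5)
hyp <- score_states(fe)
write.csv(as.data.frame(hyp), "results/tables/hypnogram.csv",
          row.names = FALSE)

ref <- hypnogram_from_blocks(truth$truth$state_blocks, 5)
acc <- mean(hyp$label == ref$label)
message(sprintf("epoch-label accuracy vs generator hypnogram: %.1f%%",
                100 * acc))
tab <- table(truth = ref$label, scored = hyp$label)
write.csv(as.data.frame(tab), "results/tables/scoring_confusion.csv",
          row.names = FALSE)
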