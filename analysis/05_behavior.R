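#!/usr/bin/env Rscript
# Score the simulated stim/sham behavioral trials: MOS quality and keyword
# intelligibility, compared across arms with rank-sum tests.
# Requires analysis/01_simulate.R (same seed).

suppressPackageStartupMessages(library(sinpipe))
trials <- read.csv("results/synthetic/behavior_trials.csv")

cat("== Behavioral stim vs sham comparison ==\n")
mos <- compare_arms(trials, "mos")
intel <- compare_arms(trials, "intelligibility")
res <- rbind(cbind(measure = "mos", mos),
             cbind(measure = "intelligibility", intel))
write.csv(res, "results/behavior_results.csv", row.names = FALSE)

cat(sprintf("MOS: stim %.2f vs sham %.2f, rank-sum p = %.2g (n = %d/arm)\n",
            mos$mean_stim, mos$mean_sham, mos$p, mos$n_stim))
cat(sprintf("intelligibility: stim %.1f%% vs sham %.1f%%, p = %.2g\n",
            intel$mean_stim, intel$mean_sham, intel$p))
cat("table written to results/behavior_results.csv\n")
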