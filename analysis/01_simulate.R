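#!/usr/bin/env Rscript
# Generate the synthetic study bundle with known ground truth: the inputs
# every later analysis consumes. Writes plain-text tables under
# results/synthetic/.

suppressPackageStartupMessages(library(sinpipe))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("== Synthetic bundle (seed", seed, ") ==\n")

## Ground-truth receptive fields: 20 sites, distinct best frequencies and
## latencies, alternating narrowband (HG-like) / broadband (PT-like)
n_sites <- 20
lat_order <- (7 * seq_len(n_sites)) %% n_sites
truths <- lapply(seq_len(n_sites), function(i) {
  gt_strf(bf_band = 2 + 12 * (i - 1) / (n_sites - 1),
          latency_ms = 40 + 120 * lat_order[i] / (n_sites - 1),
          bw_bands = if (i %% 2 == 0) 3.5 else 0.9)
})
truth_tab <- data.frame(
  site = seq_len(n_sites),
  true_bf_band = sapply(truths, `[[`, "true_bf"),
  true_latency_ms = sapply(truths, `[[`, "true_latency"),
  type = ifelse(seq_len(n_sites) %% 2 == 0, "broadband", "narrowband")
)
write.csv(truth_tab, file.path(out, "strf_ground_truth.csv"),
          row.names = FALSE)
cat("wrote", nrow(truth_tab), "ground-truth STRF sites\n")

## Stimulus and responses at 10 dB SNR (10 min @ 100 Hz, 16 bands)
stim <- white_noise_spectrogram(60000, 16, seed = seed)
responses <- sapply(seq_along(truths), function(i) {
  clean <- simulate_strf_responses(truths[[i]], stim, 0)
  simulate_strf_responses(truths[[i]], stim,
                          noise_sd_for_snr(clean, 10), seed = seed * 1000 + i)
})
saveRDS(list(stim = stim, responses = responses, truths = truths),
        file.path(out, "strf_bundle.rds"))
cat("simulated", ncol(responses), "site responses over",
    nrow(responses), "frames\n")

## Ground-truth connectivity motif and CCEP trials
net <- gt_network_motif(4)
write.csv(data.frame(node = seq_along(net$region_of_node),
                     region = net$region_of_node),
          file.path(out, "ccep_nodes.csv"), row.names = FALSE)
write.table(net$adjacency_true, file.path(out, "ccep_adjacency_true.csv"),
            sep = ",", row.names = FALSE, col.names = FALSE)
trials <- simulate_ccep_trials(net, 30, 512, seed = seed + 1)
saveRDS(trials, file.path(out, "ccep_trials.rds"))
cat("simulated CCEP trials:", paste(dim(trials$tensor), collapse = " x "),
    "(stim x record x trial x time)\n")

## Behavioral trials, study-sized quality effect (Condition-1-like)
spec <- behavior_effect_spec(3.2, 2.4, 0.91, 0.46, 24)
btrials <- simulate_behavior_trials(spec, seed = seed + 30)
write.csv(btrials, file.path(out, "behavior_trials.csv"), row.names = FALSE)
cat("wrote", nrow(btrials), "behavioral trials (stim/sham)\n")

## Demo audio: a two-tone probe for the cochlear front-end
fs <- 16000
t <- (0:(fs - 1)) / fs
write_wav(0.4 * (sin(2 * pi * 500 * t) + sin(2 * pi * 1000 * t)), fs,
          file.path(out, "probe_two_tones.wav"))
cat("wrote probe_two_tones.wav\n")
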