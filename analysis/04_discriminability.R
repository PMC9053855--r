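#!/usr/bin/env Rscript
# Speech/nonspeech discriminability along the auditory hierarchy:
# per-region t scores and 2-D MDS of population responses at the three
# simulated separation levels.

suppressPackageStartupMessages(library(sinpipe))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cat("== Speech vs nonspeech discriminability ==\n")
seps <- c(HG = 0.2, PT = 1, STG = 3)
rows <- list()
coords <- list()
for (i in seq_along(seps)) {
  region <- names(seps)[i]
  srm <- simulate_category_responses(10, 16, 53, seps[[i]],
                                     seed = seed + 10 + i)
  ts <- separability_tscore(srm)
  fit <- mds_2d(dissimilarity(srm), seed = seed + 20 + i)
  ratio <- cluster_separation(fit$points, srm$category)
  rows[[region]] <- data.frame(
    region = region, separation = seps[[i]], mean_t = ts$mean_t,
    se_t = ts$se_t, mds_stress = fit$stress, mds_separation_ratio = ratio)
  coords[[region]] <- data.frame(region = region, sound = seq_len(69),
                                 category = srm$category,
                                 x = fit$points[, 1], y = fit$points[, 2])
  cat(sprintf("%s: mean t = %.2f (SE %.2f), MDS stress %.3f, separation ratio %.2f\n",
              region, ts$mean_t, ts$se_t, fit$stress, ratio))
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/discriminability_by_region.csv", row.names = FALSE)
write.csv(do.call(rbind, coords), "results/mds_coordinates.csv",
          row.names = FALSE)
cat("regional ordering HG < PT < STG:",
    !is.unsorted(tab$mean_t, strictly = TRUE), "\n")
cat("MDS separation ratio monotone:",
    !is.unsorted(tab$mds_separation_ratio, strictly = TRUE), "\n")
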