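#' Default pipeline configuration
#'
#' One block per stage, every default equal to the study's stated value
#' where one exists: 512 Hz standardized rate, eight 70-150 Hz bands,
#' 100 Hz envelopes, responsive-site FDR q = 0.01, 16 spectrogram bands,
#' CCEP baseline -500 to -5 ms, blanking 0-20 ms, N1 window 20-30 ms,
#' binarization cutoff Z = 12, 30 trials per pair.
#'
#' @param seed integer master seed; stage seeds are derived from it
#' @return nested list of stage parameter blocks
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    preprocess = list(target_fs = 512, hp_cutoff = 1, line_freq = 60,
                      n_bands = 8, band_lims = c(70, 150), q = 0.01),
    audspec = list(n_bands = 128, n_reduced = 16, frame_rate = 100),
    strf = list(lags_ms = 300, folds = 5, n_sites = 20, minutes = 10,
                snr_db = 10),
    ccep = list(n_trials = 30, fs = 512, cutoff = 12,
                baseline_ms = c(-500, -5), blank_ms = c(0, 20),
                window_ms = c(20, 30), nodes_per_region = 4,
                amp_connected = 20, amp_unconnected = 2),
    discrim = list(n_speech = 16, n_nonspeech = 53,
                   separations = c(HG = 0.2, PT = 1, STG = 3),
                   sites_per_region = 10, energy_threshold_frac = 0.1),
    behavior = list(mos_mean_stim = 3.2, mos_mean_sham = 2.4,
                    keyword_p_stim = 0.91, keyword_p_sham = 0.46,
                    n_trials_per_arm = 24, mos_sd = 0.5)
  )
}

#' Run the full synthetic-demo pipeline
#'
#' Generates a synthetic bundle with known ground truth (STRF-driven
#' envelopes, CCEP trials over the three-region motif network,
#' category-structured population responses, stim/sham behavioral
#' trials), runs every analysis stage on it, and returns a summary list
#' that is a pure function of `(config, seed)`. This is the
#' one-command demonstration that the whole chain recovers its ground
#' truth; the `analysis/` scripts run the same stages with narration and
#' write tables.
#'
#' @param config a [pipeline_config()] list
#' @param quiet suppress progress messages
#' @return nested summary list with one element per stage
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  out <- list(seed = seed)

  ## STRF stage: simulate linear sites, refit, compare to truth
  say("STRF stage: simulate and re-estimate receptive fields")
  st <- config$strf
  n_frames <- round(st$minutes * 60 * 100)
  stim <- white_noise_spectrogram(n_frames, 16, seed = seed)
  n_sites <- st$n_sites
  # distinct best frequencies and (decorrelated) distinct latencies;
  # odd sites narrowband (HG-like), even sites broadband (PT-like)
  lat_order <- (7 * seq_len(n_sites)) %% n_sites
  truths <- lapply(seq_len(n_sites), function(i) {
    gt_strf(
      bf_band = 2 + 12 * (i - 1) / (n_sites - 1),
      latency_ms = 40 + 120 * lat_order[i] / (n_sites - 1),
      bw_bands = if (i %% 2 == 0) 3.5 else 0.9
    )
  })
  responses <- sapply(seq_along(truths), function(i) {
    clean <- simulate_strf_responses(truths[[i]], stim, noise_sd = 0)
    clean + with_seed(seed * 1000 + i, stats::rnorm(
      length(clean), 0, noise_sd_for_snr(clean, st$snr_db)))
  })
  fits <- fit_strf_multi(stim, responses, st$lags_ms, st$folds)
  kcor <- vapply(seq_along(fits), function(i) {
    stats::cor(as.numeric(fits[[i]]$kernel), as.numeric(truths[[i]]$kernel))
  }, numeric(1))
  tune <- lapply(fits, tuning_summary)
  bf_est <- vapply(tune, `[[`, numeric(1), "best_band")
  lat_est <- vapply(tune, `[[`, numeric(1), "latency")
  bf_true <- vapply(truths, `[[`, numeric(1), "true_bf")
  lat_true <- vapply(truths, `[[`, numeric(1), "true_latency")
  bw <- vapply(tune, `[[`, numeric(1), "bandwidth_bands")
  out$strf <- list(
    kernel_cor = kcor, mean_kernel_cor = mean(kcor),
    bf_rank_cor = stats::cor(bf_true, bf_est, method = "spearman"),
    mean_latency_err_ms = mean(abs(lat_est - lat_true)),
    mean_fit_score = mean(vapply(fits, `[[`, numeric(1), "fit_score")),
    bandwidth_narrow = mean(bw[seq_len(n_sites) %% 2 == 1]),
    bandwidth_broad = mean(bw[seq_len(n_sites) %% 2 == 0])
  )

  ## CCEP stage: motif network, trials, graph, shortest paths
  say("CCEP stage: simulate trials and rebuild the connectivity graph")
  cc <- config$ccep
  net <- gt_network_motif(cc$nodes_per_region, cc$amp_connected,
                          cc$amp_unconnected)
  trials <- simulate_ccep_trials(net, cc$n_trials, cc$fs, seed = seed + 1)
  zmat <- ccep_adjacency(trials, cc$baseline_ms, cc$blank_ms, cc$window_ms)
  cg <- build_graph(zmat, cc$cutoff, net$region_of_node)
  path <- shortest_group_path(cg, "HG", "STG")
  cmp <- group_n1_compare(zmat, net$region_of_node, c("PT", "HG"), "STG")
  out$ccep <- list(
    adjacency_exact = identical(cg$adjacency_bin, net$adjacency_true),
    n_edges = sum(cg$adjacency_bin),
    hg_to_stg_path = path,
    path_regions = net$region_of_node[path],
    path_traverses_pt = "PT" %in% net$region_of_node[path],
    pt_vs_hg_n1_means = cmp$means,
    pt_vs_hg_p = cmp$test$p.value
  )

  ## Discriminability stage: gradient of speech/nonspeech separation
  say("Discriminability stage: regional t scores and MDS")
  dc <- config$discrim
  regions <- names(dc$separations)
  t_means <- numeric(0)
  sep_ratio <- numeric(0)
  stress <- numeric(0)
  for (i in seq_along(dc$separations)) {
    srm <- simulate_category_responses(
      dc$sites_per_region, dc$n_speech, dc$n_nonspeech,
      separation = dc$separations[[i]], seed = seed + 10 + i)
    ts <- separability_tscore(srm)
    fit <- mds_2d(dissimilarity(srm), seed = seed + 20 + i)
    t_means[regions[i]] <- ts$mean_t
    sep_ratio[regions[i]] <- cluster_separation(fit$points, srm$category)
    stress[regions[i]] <- fit$stress
  }
  out$discrim <- list(region_mean_t = t_means,
                      mds_separation_ratio = sep_ratio,
                      mds_stress = stress)

  ## Behavior stage: stim vs sham scoring
  say("Behavior stage: score stim versus sham trials")
  bh <- config$behavior
  spec <- behavior_effect_spec(bh$mos_mean_stim, bh$mos_mean_sham,
                               bh$keyword_p_stim, bh$keyword_p_sham,
                               bh$n_trials_per_arm, bh$mos_sd)
  btrials <- simulate_behavior_trials(spec, seed = seed + 30)
  mos_res <- compare_arms(btrials, "mos")
  int_res <- compare_arms(btrials, "intelligibility")
  out$behavior <- list(
    mos = mos_res[, c("mean_stim", "mean_sham", "p")],
    intelligibility = int_res[, c("mean_stim", "mean_sham", "p")]
  )
  out
}

#' Write a pipeline summary as JSON
#'
#' @param summary output of [run_pipeline()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pipeline_summary <- function(summary, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
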