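#' Ground-truth spectrotemporal receptive field
#'
#' A known lag x band kernel with a Gaussian excitatory lobe (and an
#' optional delayed inhibitory lobe), used to generate linear high-gamma
#' responses whose true best frequency and latency are known by
#' construction. Narrow `bw_bands` gives a narrowband primary-cortex-like
#' kernel; large `bw_bands` a broadband kernel like those seen in the
#' planum temporale.
#'
#' @param n_lags number of lag steps (10 ms each at 100 Hz)
#' @param n_bands number of frequency bands
#' @param bf_band center band of the excitatory lobe (may be fractional)
#' @param latency_ms center latency of the excitatory lobe in ms
#' @param bw_bands spectral SD of the lobe in bands
#' @param bw_ms temporal SD of the lobe in ms
#' @param inhibitory if `TRUE`, add a negative lobe 40 ms after the
#'   excitatory one at 60% amplitude ("two-lobe" mode); default single-lobe
#' @param lag_step_ms lag grid step, default 10 ms (100 Hz)
#' @return object of class `gt_strf` with fields `kernel`, `true_bf`
#'   (band index), `true_latency` (ms)
#' @export
gt_strf <- function(n_lags = 31, n_bands = 16, bf_band = 8, latency_ms = 80,
                    bw_bands = 1.2, bw_ms = 15, inhibitory = FALSE,
                    lag_step_ms = 10) {
  stopifnot(n_lags >= 2, n_bands >= 2, bw_bands > 0, bw_ms > 0,
            bf_band >= 1, bf_band <= n_bands,
            latency_ms >= 0, latency_ms <= (n_lags - 1) * lag_step_ms)
  lags_ms <- (seq_len(n_lags) - 1) * lag_step_ms
  bands <- seq_len(n_bands)
  lobe <- function(l0, b0) {
    outer(exp(-(lags_ms - l0)^2 / (2 * bw_ms^2)),
          exp(-(bands - b0)^2 / (2 * bw_bands^2)))
  }
  kernel <- lobe(latency_ms, bf_band)
  if (inhibitory) {
    kernel <- kernel - 0.6 * lobe(latency_ms + 40, bf_band)
  }
  stopifnot(all(is.finite(kernel)))
  structure(list(kernel = kernel, lags_ms = lags_ms,
                 true_bf = bf_band, true_latency = latency_ms),
            class = "gt_strf")
}

#' Simulate high-gamma responses from a linear STRF
#'
#' The response is the linear spectrotemporal convolution of the kernel
#' with the spectrogram plus additive Gaussian noise:
#' `y[t] = sum_lag sum_band kernel[lag, band] * S[t - lag, band] + e[t]`.
#'
#' @param strf a [gt_strf()] (or any list with a lag x band `kernel`)
#' @param spectrogram an [auditory_spectrogram()] whose band count matches
#'   the kernel
#' @param noise_sd SD of the additive Gaussian noise (>= 0)
#' @param seed integer seed (draws are local to the call)
#' @return numeric response vector, one value per spectrogram frame
#' @export
simulate_strf_responses <- function(strf, spectrogram, noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0)
  k <- strf$kernel
  s <- spectrogram$energies
  if (ncol(s) != ncol(k)) {
    stop("spectrogram has ", ncol(s), " bands but kernel expects ", ncol(k))
  }
  y <- strf_predict(s, k)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  y
}

# Linear prediction sum_l sum_b k[l, b] * s[t - l + 1, b]; frames before
# stimulus onset are treated as zero energy.
strf_predict <- function(s, k) {
  n <- nrow(s)
  y <- numeric(n)
  for (l in seq_len(nrow(k))) {
    idx <- seq_len(n - l + 1)
    y[idx + l - 1] <- y[idx + l - 1] + s[idx, , drop = FALSE] %*% k[l, ]
  }
  as.numeric(y)
}

#' Noise SD giving a target SNR for a clean signal
#'
#' @param clean noiseless signal
#' @param snr_db target signal-to-noise ratio in dB
#' @return Gaussian noise SD such that `var(clean)/noise_sd^2` equals the
#'   requested SNR
#' @export
noise_sd_for_snr <- function(clean, snr_db) {
  stats::sd(clean) / sqrt(10^(snr_db / 10))
}

#' White-noise auditory spectrogram
#'
#' Spectrogram whose entries are iid half-normal energies — the flat,
#' uncorrelated stimulus under which reverse correlation is unbiased.
#'
#' @param n_frames number of frames
#' @param n_bands number of bands
#' @param frame_rate frame rate (Hz)
#' @param seed integer seed
#' @return an [auditory_spectrogram()]
#' @export
white_noise_spectrogram <- function(n_frames, n_bands = 16, frame_rate = 100,
                                    seed = 1) {
  e <- with_seed(seed, matrix(abs(stats::rnorm(n_frames * n_bands)),
                              n_frames, n_bands))
  centers <- exp(seq(log(200), log(8000), length.out = n_bands))
  auditory_spectrogram(e, centers, frame_rate)
}

#' Ground-truth directed connectivity network
#'
#' @param adjacency_true node x node binary matrix (zero diagonal)
#' @param region_of_node per-node region labels in HG/PT/STG
#' @param n1_amp_connected N1 amplitude (in units of baseline SD) injected
#'   for connected pairs; must exceed `n1_amp_unconnected`
#' @param n1_amp_unconnected amplitude for unconnected pairs (>= 0)
#' @return object of class `gt_network`
#' @export
gt_network <- function(adjacency_true, region_of_node,
                       n1_amp_connected = 20, n1_amp_unconnected = 2) {
  adjacency_true <- as.matrix(adjacency_true)
  stopifnot(
    nrow(adjacency_true) == ncol(adjacency_true),
    all(adjacency_true %in% c(0, 1)),
    all(diag(adjacency_true) == 0),
    length(region_of_node) == nrow(adjacency_true),
    all(region_of_node %in% c("HG", "PT", "STG")),
    n1_amp_unconnected >= 0,
    n1_amp_connected > n1_amp_unconnected
  )
  structure(list(adjacency_true = adjacency_true,
                 region_of_node = as.character(region_of_node),
                 n1_amp_connected = n1_amp_connected,
                 n1_amp_unconnected = n1_amp_unconnected),
            class = "gt_network")
}

#' Three-region motif network
#'
#' Builds the 12-node, 3-region ground truth with the auditory-pathway
#' motif: bidirectional HG-PT and PT-STG coupling, no direct HG-STG
#' edges, and full within-region connectivity.
#'
#' @param nodes_per_region nodes in each of HG, PT, STG (default 4)
#' @param n1_amp_connected,n1_amp_unconnected amplitudes passed to
#'   [gt_network()]
#' @return a [gt_network()]
#' @export
gt_network_motif <- function(nodes_per_region = 4, n1_amp_connected = 20,
                             n1_amp_unconnected = 2) {
  regions <- rep(c("HG", "PT", "STG"), each = nodes_per_region)
  n <- length(regions)
  adj <- matrix(0, n, n)
  connected_regions <- function(a, b) {
    (a == b) || (a == "HG" && b == "PT") || (a == "PT" && b == "HG") ||
      (a == "PT" && b == "STG") || (a == "STG" && b == "PT")
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && connected_regions(regions[i], regions[j])) adj[i, j] <- 1
    }
  }
  gt_network(adj, regions, n1_amp_connected, n1_amp_unconnected)
}

#' Simulate single-pulse stimulation trials (CCEPs)
#'
#' For every ordered node pair (stimulated, recorded), generates `n_trials`
#' trials of Gaussian baseline noise. A raised-cosine deflection of 10 ms
#' width centered 25 ms post-stimulus — the N1-like component — is added
#' with amplitude `n1_amp_connected * baseline_sd` for pairs connected in
#' the ground truth and `n1_amp_unconnected * baseline_sd` otherwise. A
#' saturating square transient covers the first 20 ms post-stimulus, as a
#' stimulation artifact would, so downstream blanking is exercised.
#'
#' @param net a [gt_network()]
#' @param n_trials trials per pair (>= 2), default 30
#' @param fs sampling rate in Hz, default 512
#' @param baseline_sd SD of the per-trial baseline noise (microvolts)
#' @param seed integer seed
#' @param pre_s,post_s seconds of data before/after the stimulus
#' @param n1_center_ms,n1_width_ms deflection center and full width (ms)
#' @param artifact_amp artifact plateau in multiples of `baseline_sd`
#' @return object of class `ccep_set`: tensor
#'   `[stim node, record node, trial, time]`, `fs`, `t0` (stimulus onset
#'   sample), `time_ms`, and node regions
#' @export
simulate_ccep_trials <- function(net, n_trials = 30, fs = 512,
                                 baseline_sd = 1, seed = 1,
                                 pre_s = 0.55, post_s = 0.25,
                                 n1_center_ms = 25, n1_width_ms = 10,
                                 artifact_amp = 200) {
  stopifnot(inherits(net, "gt_network"))
  if (n_trials < 2) stop("n_trials must be at least 2")
  if (fs * 0.010 < 5) stop("fs too low: the 20-30 ms window needs >= 5 samples")
  stopifnot(pre_s >= 0.5)
  n_nodes <- nrow(net$adjacency_true)
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  n_time <- n_pre + n_post
  t0 <- n_pre + 1L
  time_ms <- ((seq_len(n_time) - t0) / fs) * 1000
  # N1-like deflection: one-sided raised cosine, zero outside its support
  bump <- ifelse(
    abs(time_ms - n1_center_ms) < n1_width_ms / 2,
    0.5 * (1 + cos(2 * pi * (time_ms - n1_center_ms) / n1_width_ms)), 0)
  artifact <- as.numeric(time_ms >= 0 & time_ms < 20) *
    artifact_amp * baseline_sd
  tensor <- with_seed(seed, {
    x <- array(stats::rnorm(n_nodes * n_nodes * n_trials * n_time,
                            0, baseline_sd),
               dim = c(n_nodes, n_nodes, n_trials, n_time))
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        amp <- if (i == j) 0 else if (net$adjacency_true[i, j] == 1) {
          net$n1_amp_connected
        } else net$n1_amp_unconnected
        wave <- amp * baseline_sd * bump + artifact
        for (tr in seq_len(n_trials)) {
          x[i, j, tr, ] <- x[i, j, tr, ] + wave
        }
      }
    }
    x
  })
  structure(list(tensor = tensor, fs = fs, t0 = t0, time_ms = time_ms,
                 region_of_node = net$region_of_node,
                 baseline_sd = baseline_sd),
            class = "ccep_set")
}

#' Simulate category-structured population responses
#'
#' Produces a sound x site matrix of time-averaged responses in which
#' speech sounds are drawn around `+separation / 2` and nonspeech sounds
#' around `-separation / 2`, with unit within-category SD at every site —
#' so `separation` is the expected speech-minus-nonspeech difference in SD
#' units, and the expected per-site two-sample t statistic follows from
#' the usual pooled formula.
#'
#' @param n_sites number of recording sites
#' @param n_speech number of speech sounds (study value 16)
#' @param n_nonspeech number of nonspeech sounds (study value 53)
#' @param separation category mean difference in within-category SD units
#'   (>= 0)
#' @param seed integer seed
#' @return a [sound_response_matrix()]
#' @export
simulate_category_responses <- function(n_sites, n_speech = 16,
                                        n_nonspeech = 53, separation = 1,
                                        seed = 1) {
  stopifnot(separation >= 0, n_sites >= 1, n_speech >= 2, n_nonspeech >= 2)
  n_sounds <- n_speech + n_nonspeech
  category <- rep(c("speech", "nonspeech"), c(n_speech, n_nonspeech))
  mu <- ifelse(category == "speech", separation / 2, -separation / 2)
  means <- with_seed(seed, {
    matrix(stats::rnorm(n_sounds * n_sites), n_sounds, n_sites) + mu
  })
  sound_response_matrix(means, category,
                        region = rep("other", n_sites))
}

#' Behavioral effect specification
#'
#' Arm-level parameters of a stimulation-versus-sham speech-in-noise
#' block: mean opinion score (MOS, 1-5 scale) means and per-keyword
#' report probabilities for each arm.
#'
#' @param mos_mean_stim,mos_mean_sham arm MOS means, in `[1, 5]`
#' @param keyword_p_stim,keyword_p_sham per-keyword correct-report
#'   probabilities, in `[0, 1]`
#' @param n_trials_per_arm trials per arm
#' @param mos_sd latent SD of the MOS draw before rounding, default 0.5
#' @param n_keywords keywords per sentence, default 3
#' @return object of class `behavior_effect_spec`
#' @export
behavior_effect_spec <- function(mos_mean_stim, mos_mean_sham,
                                 keyword_p_stim, keyword_p_sham,
                                 n_trials_per_arm, mos_sd = 0.5,
                                 n_keywords = 3) {
  stopifnot(
    mos_mean_stim >= 1, mos_mean_stim <= 5,
    mos_mean_sham >= 1, mos_mean_sham <= 5,
    keyword_p_stim >= 0, keyword_p_stim <= 1,
    keyword_p_sham >= 0, keyword_p_sham <= 1,
    n_trials_per_arm >= 1, mos_sd >= 0, n_keywords >= 1
  )
  structure(as.list(environment()), class = "behavior_effect_spec")
}

#' Simulate stim/sham behavioral trials
#'
#' MOS ratings are Gaussian draws around the arm mean, rounded and clipped
#' to the discrete 1-5 scale. Each sentence carries `n_keywords` keywords;
#' each keyword is reported correctly with the arm's probability
#' (independent Bernoulli draws), and the reported-word string contains
#' exactly the correctly repeated keywords.
#'
#' @param spec a [behavior_effect_spec()]
#' @param seed integer seed
#' @param noise_type,snr_db,current_ma condition block labels attached to
#'   every trial
#' @return data.frame of trials: `condition`, `noise_type`, `snr_db`,
#'   `current_ma`, `sentence_keywords`, `reported_words`
#'   (space-separated strings), `mos`
#' @export
simulate_behavior_trials <- function(spec, seed = 1, noise_type = "jet",
                                     snr_db = -2.27, current_ma = 3) {
  stopifnot(inherits(spec, "behavior_effect_spec"))
  with_seed(seed, {
    one_arm <- function(condition, mos_mean, p_kw) {
      n <- spec$n_trials_per_arm
      mos <- pmin(pmax(round(stats::rnorm(n, mos_mean, spec$mos_sd)), 1), 5)
      rows <- lapply(seq_len(n), function(i) {
        kws <- sprintf("%s%02d_kw%d", condition, i, seq_len(spec$n_keywords))
        hit <- stats::runif(spec$n_keywords) < p_kw
        data.frame(
          condition = condition, noise_type = noise_type, snr_db = snr_db,
          current_ma = current_ma,
          sentence_keywords = paste(kws, collapse = " "),
          reported_words = paste(kws[hit], collapse = " "),
          mos = mos[i]
        )
      })
      do.call(rbind, rows)
    }
    rbind(one_arm("stim", spec$mos_mean_stim, spec$keyword_p_stim),
          one_arm("sham", spec$mos_mean_sham, spec$keyword_p_sham))
  })
}
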