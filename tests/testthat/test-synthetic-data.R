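test_that("STRF response simulation is an exact linear convolution", {
  spec <- toy_spectrogram(50, n_bands = 4, seed = 3)
  # zero kernel -> all-zero output
  zero <- list(kernel = matrix(0, 5, 4))
  expect_equal(simulate_strf_responses(zero, spec, 0),
               rep(0, 50))
  # identity-like kernel: single 1 at lag 0, band 3 -> copies band 3
  ident <- list(kernel = rbind(c(0, 0, 1, 0), matrix(0, 4, 4)))
  expect_equal(simulate_strf_responses(ident, spec, 0),
               as.numeric(spec$energies[, 3]))
  # general kernel matches the naive triple-loop oracle
  set.seed(9)
  k <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(simulate_strf_responses(list(kernel = k), spec, 0),
               naive_strf_convolution(k, spec$energies), tolerance = 1e-12)
  # band mismatch is an error
  expect_error(simulate_strf_responses(zero, toy_spectrogram(50, 5), 0),
               "bands")
})

test_that("generators are bit-reproducible given the seed and leave RNG alone", {
  spec <- toy_spectrogram(30)
  k <- gt_strf(n_lags = 5, n_bands = 4, bf_band = 2, latency_ms = 20)
  a <- simulate_strf_responses(k, spec, noise_sd = 1, seed = 42)
  set.seed(777)
  before <- .Random.seed
  b <- simulate_strf_responses(k, spec, noise_sd = 1, seed = 42)
  expect_identical(a, b)
  expect_identical(before, .Random.seed)
  net <- gt_network_motif(2)
  expect_identical(simulate_ccep_trials(net, 3, 512, seed = 5)$tensor,
                   simulate_ccep_trials(net, 3, 512, seed = 5)$tensor)
  expect_false(identical(simulate_ccep_trials(net, 3, 512, seed = 5)$tensor,
                         simulate_ccep_trials(net, 3, 512, seed = 6)$tensor))
})

test_that("ground-truth STRF kernels satisfy their invariants", {
  k <- gt_strf(bf_band = 8, latency_ms = 80, bw_bands = 1.2)
  expect_true(all(is.finite(k$kernel)))
  # single-lobe mode: positive entries form one 4-connected region
  mask <- k$kernel > 1e-10 * max(k$kernel)
  region <- sinpipe:::largest_connected_region(mask)
  expect_true(all(mask == region))
  expect_error(gt_strf(bf_band = 40), "bf_band")
})

test_that("CCEP trial simulation matches its construction", {
  # null network: amplitudes ~0 everywhere -> N1 statistics near zero
  net0 <- gt_network(matrix(0, 3, 3), c("HG", "PT", "STG"),
                     n1_amp_connected = 1e-9, n1_amp_unconnected = 0)
  set0 <- simulate_ccep_trials(net0, 30, 512, seed = 2)
  z0 <- ccep_adjacency(set0)
  expect_lt(max(z0), 4)
  # trial mean converges to the injected waveform (3 SE at n = 1000)
  adj <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  net <- gt_network(adj, c("HG", "PT"), n1_amp_connected = 12)
  big <- simulate_ccep_trials(net, 1000, 512, baseline_sd = 1, seed = 3)
  avg <- colMeans(big$tensor[1, 2, , ])
  se <- 1 / sqrt(1000)
  peak_idx <- which.min(abs(big$time_ms - 25))
  # injected raised-cosine value at the nearest sample to 25 ms
  injected <- 12 * 0.5 * (1 + cos(2 * pi * (big$time_ms[peak_idx] - 25) / 10))
  expect_lt(abs(avg[peak_idx] - injected), 3 * se)
  base_idx <- big$time_ms < -30
  expect_lt(max(abs(avg[base_idx])), 4.5 * se)
  expect_error(simulate_ccep_trials(net, 1), "n_trials")
})

test_that("category response simulation has the stated moments", {
  # study-sized set: 16 speech + 53 nonspeech = 69 sounds
  srm <- simulate_category_responses(5, 16, 53, separation = 3, seed = 1)
  expect_equal(nrow(srm$means), 69)
  expect_equal(sum(srm$category == "speech"), 16)
  # mean per-site t within sampling error of the closed-form value
  ts <- sapply(1:40, function(s) {
    separability_tscore(
      simulate_category_responses(8, 16, 53, separation = 3, seed = s))$mean_t
  })
  t_closed <- 3 / sqrt(1 / 16 + 1 / 53)
  expect_lt(abs(mean(ts) - t_closed), 3 * sd(ts) / sqrt(length(ts)) + 0.2)
  # null separation: per-site t distributed as a null t
  t0 <- separability_tscore(
    simulate_category_responses(200, 16, 53, separation = 0, seed = 2))
  expect_lt(abs(t0$mean_t), 3 * t0$se_t + 0.05)
})

test_that("behavioral trial simulation respects its arm parameters", {
  sp <- behavior_effect_spec(3.2, 2.4, 1, 1, 10)
  tr <- simulate_behavior_trials(sp, seed = 1)
  expect_equal(nrow(tr), 20)
  expect_true(all(tr$mos %in% 1:5))
  # p = 1 in both arms -> 100% intelligibility everywhere
  res <- compare_arms(tr, "intelligibility")
  expect_equal(res$mean_stim, 100)
  expect_equal(res$mean_sham, 100)
  # null MOS means -> rank-sum p roughly uniform over replicates
  sp0 <- behavior_effect_spec(2.4, 2.4, .5, .5, 20)
  p0 <- sapply(1:60, function(s) {
    compare_arms(simulate_behavior_trials(sp0, seed = s), "mos")$p
  })
  expect_gt(mean(p0), 0.3)
  expect_gt(mean(p0 > 0.5), 0.3)
  expect_error(behavior_effect_spec(0.5, 2, .5, .5, 10))
})
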