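test_that("sound means gate silence by spectrogram energy", {
  # envelope: 2 channels x 12 frames; sound 1 has silent frames with
  # absurd envelope values that must be excluded by the energy gate
  env_mat <- rbind(c(rep(1, 4), rep(100, 2), rep(3, 6)),
                   c(rep(2, 4), rep(100, 2), rep(5, 6)))
  energy <- c(rep(1, 4), rep(0.0001, 2), rep(1, 6))
  spec <- auditory_spectrogram(matrix(energy / 4, 12, 4),
                               band_centers = c(100, 200, 400, 800))
  events <- data.frame(sound = c("a", "b"), onset = c(1, 7), offset = c(6, 12),
                       category = c("speech", "nonspeech"))
  srm <- sound_means(hg_envelope(env_mat), events, spec)
  expect_equal(srm$means, rbind(c(1, 2), c(3, 5)), ignore_attr = TRUE)
  # threshold -Inf -> plain ungated mean
  srm_all <- sound_means(hg_envelope(env_mat), events, spec,
                         energy_threshold_frac = -Inf)
  expect_equal(srm_all$means[1, ], colMeans(t(env_mat[, 1:6])),
               ignore_attr = TRUE)
  # a sound with no above-threshold frames errors by name
  spec0 <- auditory_spectrogram(matrix(c(rep(1, 6), rep(0, 6)), 12, 1),
                                band_centers = 100)
  expect_error(sound_means(hg_envelope(env_mat), events, spec0,
                           energy_threshold_frac = 2),
               "a")
  bad <- events; bad$offset[2] <- 40
  expect_error(sound_means(hg_envelope(env_mat), bad, spec), "outside")
})

test_that("dissimilarity is a Euclidean metric computed per region", {
  m <- rbind(c(0, 0), c(3, 4), c(0, 0))
  srm <- sound_response_matrix(m, c("speech", "nonspeech", "nonspeech"),
                               c("PT", "PT"))
  d <- dissimilarity(srm, "PT")
  expect_equal(d[1, 2], 5)           # 3-4-5 triangle
  expect_equal(d[1, 3], 0)           # identical rows
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_error(dissimilarity(srm, "STG"), "no sites")
  # random matrix matches the naive double loop, and triangle inequality
  set.seed(31)
  r <- matrix(rnorm(15), 5, 3)
  srm2 <- sound_response_matrix(r, rep(c("speech", "nonspeech"), c(2, 3)),
                                rep("HG", 3))
  d2 <- dissimilarity(srm2, "HG")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d2[i, j], sqrt(sum((r[i, ] - r[j, ])^2)))
  }
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
  }
})

test_that("MDS reproduces realizable 2-D configurations almost exactly", {
  set.seed(41)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  fit <- mds_2d(d, seed = 1)
  expect_lt(fit$stress, 1e-3)
  expect_true(all(diff(fit$trace) <= 1e-12))   # monotone descent
  # recovered distances match the input up to rigid motion
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-4,
               ignore_attr = TRUE)
  skip_if_not_installed("vegan")
  pr <- vegan::procrustes(pts, fit$points)
  expect_lt(sqrt(mean(residuals(pr)^2)) / sd(pts), 1e-2)
})

test_that("MDS handles symmetric and non-embeddable inputs correctly", {
  # 3 equidistant sounds -> equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  fit3 <- mds_2d(d3, seed = 2)
  expect_lt(fit3$stress, 1e-6)
  sides <- as.numeric(dist(fit3$points))
  expect_equal(sides, rep(sides[1], 3), tolerance = 1e-4)
  # 4-D simplex cannot embed in 2-D: stress stays positive
  d5 <- matrix(1, 5, 5); diag(d5) <- 0
  fit5 <- mds_2d(d5, seed = 3, n_restarts = 10)
  expect_gt(fit5$stress, 0.05)
  # asymmetric input is refused
  bad <- d3; bad[1, 2] <- 2
  expect_error(mds_2d(bad, 1), "symmetric")
  # determinism given seed
  expect_identical(mds_2d(d5, seed = 3)$points, mds_2d(d5, seed = 3)$points)
})

test_that("separability t scores match the closed form and the gradient", {
  # hand-computed toy: speech {2, 3}, nonspeech {0, 1}, pooled SD
  m <- matrix(c(2, 3, 0, 1), 4, 1)
  srm <- sound_response_matrix(m, c("speech", "speech", "nonspeech",
                                    "nonspeech"), "STG")
  ts <- separability_tscore(srm, "STG")
  sp2 <- 0.5  # both groups have variance 0.5
  t_manual <- (2.5 - 0.5) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(ts$mean_t, t_manual)
  expect_error(separability_tscore(
    sound_response_matrix(m, c("speech", rep("nonspeech", 3)), "STG"),
    "STG"), "2 sounds")
  # simulated gradient reproduces the regional ordering
  t_by_region <- sapply(c(HG = 0.2, PT = 1, STG = 3), function(sep) {
    separability_tscore(
      simulate_category_responses(10, 16, 53, sep, seed = 51))$mean_t
  })
  expect_true(t_by_region["HG"] < t_by_region["PT"])
  expect_true(t_by_region["PT"] < t_by_region["STG"])
})

test_that("MDS cluster separation grows with the simulated separation", {
  ratios <- sapply(c(0.2, 1, 3), function(sep) {
    srm <- simulate_category_responses(10, 16, 53, sep, seed = 61)
    fit <- mds_2d(dissimilarity(srm), seed = 62)
    cluster_separation(fit$points, srm$category)
  })
  expect_true(all(diff(ratios) > 0))
})
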