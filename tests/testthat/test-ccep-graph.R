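test_that("mean CCEP normalization and blanking behave as constructed", {
  adj <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  net <- gt_network(adj, c("HG", "PT"), n1_amp_connected = 12,
                    n1_amp_unconnected = 0.001)
  set <- simulate_ccep_trials(net, 30, 512, baseline_sd = 2, seed = 6)
  # injected 12-SD bump reads out as Z ~ 12 (3 SE over trials)
  cc <- mean_ccep(set, 1, 2)
  z <- n1_statistic(cc)
  # slack beyond 3 SE: the 10 ms raised cosine is sampled at 512 Hz, so
  # the largest sampled value falls slightly below the nominal peak
  expect_lt(abs(z - 12), 3 / sqrt(30) + 0.2)
  # blanked window is excluded entirely
  expect_true(all(is.na(cc$z[cc$time_ms >= 0 & cc$time_ms < 20])))
  # statistics are invariant to artifact amplitude (blanking property)
  set2 <- simulate_ccep_trials(net, 30, 512, baseline_sd = 2, seed = 6,
                               artifact_amp = 5000)
  expect_equal(n1_statistic(mean_ccep(set2, 1, 2)), z)
  # null pair: Z values small
  expect_lt(n1_statistic(mean_ccep(set, 2, 1)), 4)
  # degenerate (constant) channel errors
  setc <- set
  setc$tensor[1, 2, , ] <- 1
  expect_error(mean_ccep(setc, 1, 2), "degenerate")
})

test_that("the N1 statistic is a polarity-agnostic window maximum", {
  tm <- seq(-500, 100, by = 2)
  z <- numeric(length(tm))
  expect_equal(n1_statistic(list(z = z, time_ms = tm)), 0)
  # negative deflection -15 at 25 ms -> 15
  z1 <- z; z1[tm == 26] <- -15
  expect_equal(n1_statistic(list(z = z1, time_ms = tm)), 15)
  # two peaks +8 at 22 ms, -11 at 28 ms -> 11 (brute force over window)
  z2 <- z; z2[tm == 22] <- 8; z2[tm == 28] <- -11
  win <- tm >= 20 & tm < 30
  expect_equal(n1_statistic(list(z = z2, time_ms = tm)), max(abs(z2[win])))
  expect_equal(n1_statistic(list(z = z2, time_ms = tm)), 11)
  # sign flip invariance
  expect_equal(n1_statistic(list(z = -z2, time_ms = tm)), 11)
  # window boundary is half-open: a peak exactly at 30 ms is excluded
  z3 <- z; z3[tm == 30] <- 99; z3[tm == 24] <- 5
  expect_equal(n1_statistic(list(z = z3, time_ms = tm)), 5)
  expect_error(n1_statistic(list(z = z[1:10], time_ms = tm[1:10])), "window")
})

test_that("graph binarization follows the >= cutoff rule and is monotone", {
  zm <- matrix(0, 3, 3)
  expect_equal(sum(build_graph(zm)$adjacency_bin), 0)
  # boundary: exactly Z = 12 is an edge under the inclusive rule
  zm[1, 2] <- 12; zm[2, 3] <- 11.999; zm[3, 1] <- 20
  g <- build_graph(zm, cutoff = 12)
  expect_equal(g$adjacency_bin[1, 2], 1)
  expect_equal(g$adjacency_bin[2, 3], 0)
  expect_error(build_graph(zm, cutoff = 0), "positive")
  # edge sets shrink as the cutoff grows
  set.seed(13)
  zr <- matrix(runif(36, 0, 20), 6, 6)
  cuts <- c(5, 8, 12, 15)
  edges <- lapply(cuts, function(cc) build_graph(zr, cc)$adjacency_bin)
  for (i in 2:length(cuts)) {
    expect_true(all(edges[[i]] <= edges[[i - 1]]))
  }
})

test_that("the simulated chain is recovered exactly and robustly over cutoffs", {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- 1; adj[2, 3] <- 1  # HG -> PT -> STG
  net <- gt_network(adj, c("HG", "PT", "STG"), 20, 2)
  set <- simulate_ccep_trials(net, 30, 512, seed = 9)
  zm <- ccep_adjacency(set)
  for (cutoff in c(5, 8, 12, 15)) {
    g <- build_graph(zm, cutoff, net$region_of_node)
    expect_equal(g$adjacency_bin, adj)
  }
  path <- shortest_group_path(build_graph(zm, 12, net$region_of_node),
                              "HG", "STG")
  expect_equal(path, c(1, 2, 3))
})

test_that("force-directed layout reflects connectivity structure", {
  # two disconnected cliques end up far apart
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  g <- build_graph(adj * 20, 12)
  xy <- layout_force(g, seed = 3)
  expect_identical(xy, layout_force(g, seed = 3))
  c1 <- colMeans(xy[1:3, ]); c2 <- colMeans(xy[4:6, ])
  intra <- max(dist(xy[1:3, ]), dist(xy[4:6, ]))
  expect_gt(sqrt(sum((c1 - c2)^2)), intra)
  # connected pairs sit closer than unconnected pairs on average
  dmat <- as.matrix(dist(xy))
  conn <- adj[upper.tri(adj)] == 1
  dvec <- dmat[upper.tri(dmat)]
  expect_lt(mean(dvec[conn]), mean(dvec[!conn]))
  # complete graph: roughly equidistant nodes
  full <- matrix(20, 5, 5); diag(full) <- 0
  xyf <- layout_force(build_graph(full, 12), seed = 1)
  df <- dist(xyf)
  expect_lt(sd(df) / mean(df), 0.5)
  # single node: no failure
  expect_equal(dim(layout_force(build_graph(matrix(0, 1, 1), 12), 1)),
               c(1, 2))
})

test_that("group shortest paths match exhaustive enumeration on small digraphs", {
  set.seed(17)
  regions_pool <- c("HG", "PT", "STG")
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    adj <- matrix(rbinom(n * n, 1, 0.25), n, n)
    diag(adj) <- 0
    regions <- sample(regions_pool, n, replace = TRUE)
    if (!all(c("HG", "STG") %in% regions)) next
    g <- build_graph(adj * 20, 12, regions)
    path <- shortest_group_path(g, "HG", "STG")
    oracle <- brute_force_min_hops(adj, which(regions == "HG"),
                                   which(regions == "STG"))
    if (is.null(path)) {
      expect_true(is.infinite(oracle))
    } else {
      expect_equal(length(path) - 1, oracle)
      # returned path is a real directed path with the right endpoints
      expect_equal(g$regions[path[1]], "HG")
      expect_equal(g$regions[path[length(path)]], "STG")
      if (length(path) > 1) {
        steps <- cbind(path[-length(path)], path[-1])
        expect_true(all(adj[steps] == 1))
      }
    }
  }
  expect_error(shortest_group_path(build_graph(matrix(0, 2, 2) , 12,
                                               c("HG", "PT")), "HG", "XX"),
               "unknown region")
})

test_that("motif network: HG reaches STG only through PT, PT directly", {
  net <- gt_network_motif(4)
  set <- simulate_ccep_trials(net, 30, 512, seed = 12)
  g <- build_graph(ccep_adjacency(set), 12, net$region_of_node)
  expect_equal(g$adjacency_bin, net$adjacency_true)
  hg_stg <- shortest_group_path(g, "HG", "STG")
  expect_true("PT" %in% g$regions[hg_stg[-c(1, length(hg_stg))]])
  pt_stg <- shortest_group_path(g, "PT", "STG")
  expect_equal(length(pt_stg), 2)
  expect_false("HG" %in% g$regions[pt_stg])
})

test_that("group N1 comparison separates strong from weak stimulation", {
  # identical null distributions -> p not systematically small
  set.seed(23)
  regions <- rep(c("PT", "HG", "STG"), each = 4)
  p0 <- sapply(1:40, function(i) {
    zm <- matrix(abs(rnorm(144, 5, 1)), 12, 12)
    group_n1_compare(zm, regions)$test$p.value
  })
  expect_gt(mean(p0), 0.3)
  # constructed difference: PT->STG 20 vs HG->STG 5
  zm <- matrix(abs(rnorm(144, 1, 0.2)), 12, 12)
  zm[regions == "PT", regions == "STG"] <- rnorm(16, 20, 1)
  zm[regions == "HG", regions == "STG"] <- rnorm(16, 5, 1)
  res <- group_n1_compare(zm, regions)
  expect_gt(res$means["PT"], res$means["HG"])
  expect_lt(res$test$p.value, 0.001)
  # degenerate single-value groups are refused
  expect_error(group_n1_compare(matrix(1, 2, 2), c("PT", "STG"),
                                c("PT", "HG")),
               "empty|fewer")
})
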