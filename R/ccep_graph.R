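#' Mean normalized CCEP waveform for one stimulated/recorded pair
#'
#' Averages trials, blanks the stimulation-artifact window (first 20 ms
#' post-stimulus, set to `NA` and excluded from every statistic), and
#' Z-normalizes the trial-mean waveform by the mean and SD of the
#' pre-stimulus baseline (-500 to -5 ms). Baseline statistics are pooled
#' over all trials' baseline samples, so the Z of an injected deflection
#' of `k` baseline SDs is approximately `k` irrespective of trial count.
#'
#' @param set a `ccep_set` (see [simulate_ccep_trials()])
#' @param stim_node,record_node node indices
#' @param baseline_ms baseline window relative to the stimulus, default
#'   `c(-500, -5)` ms
#' @param blank_ms artifact blanking window, default `c(0, 20)` ms
#'   (half-open)
#' @return list: `z` (normalized waveform, `NA` in the blanked window),
#'   `time_ms`, `baseline_mean`, `baseline_sd`
#' @export
mean_ccep <- function(set, stim_node, record_node,
                      baseline_ms = c(-500, -5), blank_ms = c(0, 20)) {
  stopifnot(inherits(set, "ccep_set"))
  tm <- set$time_ms
  if (baseline_ms[1] < min(tm)) {
    stop("baseline window starts before the pre-stimulus data")
  }
  trials <- set$tensor[stim_node, record_node, , ]
  if (!is.matrix(trials)) trials <- matrix(trials, nrow = 1)
  base_idx <- tm >= baseline_ms[1] & tm <= baseline_ms[2]
  base_vals <- trials[, base_idx]
  mu <- mean(base_vals)
  sdv <- stats::sd(as.numeric(base_vals))
  if (sdv == 0) stop("degenerate channel: zero baseline SD")
  avg <- colMeans(trials)
  z <- (avg - mu) / sdv
  z[tm >= blank_ms[1] & tm < blank_ms[2]] <- NA
  list(z = z, time_ms = tm, baseline_mean = mu, baseline_sd = sdv)
}

#' N1 statistic of a normalized CCEP
#'
#' Maximum absolute Z over the half-open window `[20, 30)` ms
#' post-stimulus, the early sharp CCEP component. The absolute value makes
#' the statistic polarity-agnostic, since the early deflection can be
#' negative or positive.
#'
#' @param ccep output of [mean_ccep()] (fields `z` and `time_ms`)
#' @param window_ms N1 window, default `c(20, 30)` ms, half-open
#' @return nonnegative scalar Z
#' @export
n1_statistic <- function(ccep, window_ms = c(20, 30)) {
  idx <- ccep$time_ms >= window_ms[1] & ccep$time_ms < window_ms[2]
  vals <- ccep$z[idx]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("N1 window [", window_ms[1], ", ", window_ms[2],
         ") ms contains no samples at this sampling rate")
  }
  max(abs(vals))
}

#' N1 adjacency matrix of a CCEP set
#'
#' Fills the stim x record matrix with the N1 statistic of every ordered
#' pair (rows = stimulated node, columns = recorded node); the diagonal is
#' zero by convention (no self-connectivity).
#'
#' @param set a `ccep_set`
#' @inheritParams mean_ccep
#' @inheritParams n1_statistic
#' @return square numeric matrix of Z values
#' @export
ccep_adjacency <- function(set, baseline_ms = c(-500, -5),
                           blank_ms = c(0, 20), window_ms = c(20, 30)) {
  n <- dim(set$tensor)[1]
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      z[i, j] <- n1_statistic(
        mean_ccep(set, i, j, baseline_ms, blank_ms), window_ms)
    }
  }
  z
}

#' Threshold an N1 adjacency matrix into a directed connectivity graph
#'
#' Binarizes at `Z >= cutoff` (boundary inclusive) and builds the directed
#' graph stimulated -> recorded over electrode nodes. Both the continuous
#' and binary matrices are retained.
#'
#' @param adjacency_z stim x record matrix of N1 Z values
#' @param cutoff Z threshold, default 12 (results should be stable for
#'   cutoffs across 5-15 on well-separated networks)
#' @param regions optional per-node region labels
#' @return object of class `connectivity_graph`: `graph` (igraph),
#'   `adjacency_z`, `adjacency_bin`, `cutoff`, `regions`
#' @export
build_graph <- function(adjacency_z, cutoff = 12, regions = NULL) {
  adjacency_z <- as.matrix(adjacency_z)
  stopifnot(nrow(adjacency_z) == ncol(adjacency_z))
  if (cutoff <= 0) stop("cutoff must be positive")
  adj_bin <- (adjacency_z >= cutoff) * 1
  diag(adj_bin) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj_bin, mode = "directed")
  if (is.null(regions)) regions <- rep("other", nrow(adj_bin))
  igraph::V(g)$region <- regions
  igraph::V(g)$name <- as.character(seq_len(nrow(adj_bin)))
  structure(list(graph = g, adjacency_z = adjacency_z,
                 adjacency_bin = adj_bin, cutoff = cutoff,
                 regions = regions),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("connectivity_graph: %d nodes, %d directed edges, cutoff Z=%g\n",
              nrow(x$adjacency_bin), sum(x$adjacency_bin), x$cutoff))
  invisible(x)
}

#' Force-directed layout of a connectivity graph
#'
#' Fruchterman-Reingold spring-electrical layout: connected nodes attract,
#' all nodes repel, so graph distance maps to plot distance. Deterministic
#' given the seed.
#'
#' @param cg a `connectivity_graph`
#' @param seed integer seed
#' @return node x 2 coordinate matrix
#' @export
layout_force <- function(cg, seed = 1) {
  stopifnot(inherits(cg, "connectivity_graph"))
  g <- cg$graph
  if (igraph::vcount(g) == 0) stop("graph has no nodes")
  with_seed(seed, igraph::layout_with_fr(g, dim = 2))
}

#' Shortest directed path between two anatomic groups
#'
#' Minimal-hop directed path (unit edge weights) minimized over all
#' (source-region node, target-region node) pairs. Ties are broken
#' lexicographically by node index: among minimal endpoint pairs the
#' smallest (source, target) is taken, and the path itself is the
#' lexicographically smallest geodesic (each step takes the
#' lowest-indexed neighbor that still lies on a shortest path).
#'
#' @param cg a `connectivity_graph` with region labels
#' @param source_region,target_region region labels present in the graph
#' @return integer vector of node indices from source to target, or `NULL`
#'   if no target-region node is reachable
#' @export
shortest_group_path <- function(cg, source_region, target_region) {
  stopifnot(inherits(cg, "connectivity_graph"))
  regions <- cg$regions
  for (r in c(source_region, target_region)) {
    if (!r %in% regions) stop("unknown region label: ", r)
  }
  src <- which(regions == source_region)
  tgt <- which(regions == target_region)
  d <- igraph::distances(cg$graph, mode = "out")
  best <- Inf
  best_pair <- NULL
  for (s in sort(src)) {
    for (t in sort(tgt)) {
      if (s != t && d[s, t] < best) {
        best <- d[s, t]
        best_pair <- c(s, t)
      }
    }
  }
  if (is.null(best_pair) || !is.finite(best)) return(NULL)
  # lexicographically smallest geodesic from s to t
  adj <- cg$adjacency_bin
  path <- best_pair[1]
  cur <- best_pair[1]
  t <- best_pair[2]
  while (cur != t) {
    nbrs <- which(adj[cur, ] == 1)
    nxt <- nbrs[d[nbrs, t] == d[cur, t] - 1][1]
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' Compare N1 strength in a target region between two stimulated groups
#'
#' Collects the N1 adjacency values from each stimulated group's nodes to
#' the recorded target-region nodes and compares the two samples with a
#' two-sample t test (e.g. planum temporale versus Heschl's gyrus
#' stimulation recorded in superior temporal gyrus).
#'
#' @param adjacency_z stim x record N1 matrix
#' @param regions per-node region labels
#' @param stim_groups two region labels whose stimulation is compared
#' @param record_group region whose recorded responses are compared
#' @param var_equal passed to [stats::t.test()]
#' @return list: `samples` (named list of the two Z samples), `means`,
#'   `test` (htest)
#' @export
group_n1_compare <- function(adjacency_z, regions,
                             stim_groups = c("PT", "HG"),
                             record_group = "STG", var_equal = FALSE) {
  stopifnot(length(stim_groups) == 2)
  rec <- which(regions == record_group)
  if (length(rec) == 0) stop("empty record group: ", record_group)
  samples <- lapply(stim_groups, function(g) {
    stim <- which(regions == g)
    if (length(stim) == 0) stop("empty stim group: ", g)
    vals <- adjacency_z[stim, setdiff(rec, stim), drop = FALSE]
    as.numeric(vals)
  })
  names(samples) <- stim_groups
  if (any(lengths(samples) < 2)) {
    stop("fewer than 2 N1 values in a group; test refused")
  }
  tt <- stats::t.test(samples[[1]], samples[[2]], var.equal = var_equal)
  list(samples = samples, means = vapply(samples, mean, numeric(1)),
       test = tt)
}
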