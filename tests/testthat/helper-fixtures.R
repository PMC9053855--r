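# Shared fixture builders; everything is generated in code at test time.

# Tiny deterministic spectrogram with given dimensions.
toy_spectrogram <- function(n_frames, n_bands = 4, seed = 1, frame_rate = 100) {
  set.seed(seed)
  sinpipe::auditory_spectrogram(
    matrix(abs(rnorm(n_frames * n_bands)), n_frames, n_bands),
    band_centers = 100 * 2^seq(0, 3, length.out = n_bands),
    frame_rate = frame_rate
  )
}

# Naive triple-loop spectrotemporal convolution oracle.
naive_strf_convolution <- function(kernel, spec_energies) {
  n <- nrow(spec_energies)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (l in seq_len(nrow(kernel))) {
      if (t - l + 1 >= 1) {
        for (b in seq_len(ncol(kernel))) {
          y[t] <- y[t] + kernel[l, b] * spec_energies[t - l + 1, b]
        }
      }
    }
  }
  y
}

# Exhaustive DFS over simple paths: minimal hop count between node sets,
# Inf when unreachable. Oracle for shortest_group_path.
brute_force_min_hops <- function(adj, sources, targets) {
  n <- nrow(adj)
  best <- Inf
  recurse <- function(node, visited, hops) {
    if (hops >= best) return()
    if (node %in% targets && hops > 0) {
      best <<- min(best, hops)
      return()
    }
    if (node %in% targets && hops == 0 && length(intersect(sources, targets)) > 0) {
      # source that is itself a target: zero-hop path
      best <<- 0
      return()
    }
    for (nxt in which(adj[node, ] == 1)) {
      if (!visited[nxt]) {
        visited[nxt] <- TRUE
        recurse(nxt, visited, hops + 1)
        visited[nxt] <- FALSE
      }
    }
  }
  for (s in sources) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    recurse(s, visited, 0)
  }
  best
}

# A 512 Hz single-channel recording from a waveform function of time.
sine_recording <- function(f, dur_s = 8, fs = 512, amp = 1) {
  t <- (0:(fs * dur_s - 1)) / fs
  sinpipe::recording(matrix(amp * sin(2 * pi * f * t), nrow = 1), fs)
}
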