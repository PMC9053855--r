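#' Sound x site response-matrix container
#'
#' Time-averaged high-gamma responses, one row per sound, one column per
#' recording site, with per-sound category (speech/nonspeech) and per-site
#' region labels.
#'
#' @param means sound x site numeric matrix
#' @param category per-sound labels in `{speech, nonspeech}`
#' @param region per-site region labels
#' @return object of class `sound_response_matrix`
#' @export
sound_response_matrix <- function(means, category, region) {
  means <- as.matrix(means)
  stopifnot(
    nrow(means) == length(category), ncol(means) == length(region),
    all(category %in% c("speech", "nonspeech")),
    !anyNA(means)
  )
  structure(list(means = means, category = as.character(category),
                 region = as.character(region)),
            class = "sound_response_matrix")
}

#' @export
print.sound_response_matrix <- function(x, ...) {
  cat(sprintf("sound_response_matrix: %d sounds (%d speech) x %d sites\n",
              nrow(x$means), sum(x$category == "speech"), ncol(x$means)))
  invisible(x)
}

#' Silence-gated time-averaged response to each sound
#'
#' For every sound and site, averages the envelope over the sound's frames
#' whose total spectrogram energy is above threshold, excluding the brief
#' silent segments inside a stimulus. The default threshold is 10% of the
#' sound's maximum frame energy; `-Inf` disables gating (plain time
#' average).
#'
#' @param env an [hg_envelope()] (channel x frame)
#' @param events data.frame with one row per sound: `sound`, `onset`,
#'   `offset` (frame indices, inclusive), `category`
#' @param spectrogram an [auditory_spectrogram()] aligned with `env`, used
#'   only for the frame-energy gate
#' @param energy_threshold_frac fraction of each sound's max frame energy
#'   (default 0.1), or `-Inf` for no gating
#' @return a [sound_response_matrix()] (region labels from `env`
#'   metadata when present)
#' @export
sound_means <- function(env, events, spectrogram,
                        energy_threshold_frac = 0.1) {
  stopifnot(inherits(env, "hg_envelope"),
            all(c("sound", "onset", "offset", "category") %in% names(events)))
  frame_energy <- rowSums(spectrogram$energies)
  n_frames <- ncol(env$env)
  means <- t(vapply(seq_len(nrow(events)), function(i) {
    frames <- events$onset[i]:events$offset[i]
    if (events$onset[i] < 1 || events$offset[i] > n_frames) {
      stop("event frames outside the recording for sound ", events$sound[i])
    }
    thr <- energy_threshold_frac * max(frame_energy[frames])
    keep <- frames[frame_energy[frames] >= thr]
    if (length(keep) == 0) {
      stop("no above-threshold frames for sound ", events$sound[i])
    }
    rowMeans(env$env[, keep, drop = FALSE])
  }, numeric(nrow(env$env))))
  if (nrow(env$env) == 1) means <- matrix(means, ncol = 1)
  region <- if (!is.null(env$channel_meta)) env$channel_meta$region else {
    rep("other", ncol(means))
  }
  sound_response_matrix(means, events$category, region)
}

#' Euclidean dissimilarity between sounds over a region's sites
#'
#' @param srm a [sound_response_matrix()]
#' @param region region label whose sites are used; `NULL` (default) uses
#'   all sites
#' @return symmetric sound x sound distance matrix with zero diagonal
#' @export
dissimilarity <- function(srm, region = NULL) {
  stopifnot(inherits(srm, "sound_response_matrix"))
  cols <- if (is.null(region)) seq_along(srm$region) else {
    which(srm$region == region)
  }
  if (length(cols) == 0) stop("no sites in region: ", region)
  as.matrix(stats::dist(srm$means[, cols, drop = FALSE]))
}

#' Two-dimensional MDS minimizing Kruskal stress-1
#'
#' Metric multidimensional scaling by SMACOF stress majorization: the
#' configuration is updated by the Guttman transform, which never
#' increases the raw stress, until relative improvement falls below
#' `tol`. Kruskal's normalized stress-1,
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j} (\delta_{ij} - d_{ij})^2 /
#'   \sum_{i<j} \delta_{ij}^2},}
#' is reported, and the optimizer is restarted from `n_restarts` seeded
#' random configurations, keeping the best. The per-iteration stress trace
#' of the winning restart is returned so monotone descent can be checked.
#'
#' @param dissim symmetric nonnegative dissimilarity matrix, zero diagonal
#' @param seed integer seed (controls the random restarts)
#' @param n_restarts number of random initializations, default 10
#' @param max_iter,tol optimizer controls
#' @return list: `points` (n x 2), `stress` (Kruskal stress-1, in
#'   `[0, 1]`), `trace` (stress per iteration)
#' @export
mds_2d <- function(dissim, seed = 1, n_restarts = 10, max_iter = 500,
                   tol = 1e-10) {
  dissim <- as.matrix(dissim)
  n <- nrow(dissim)
  if (!isTRUE(all.equal(dissim, t(dissim))) || any(dissim < 0) ||
      any(diag(dissim) != 0)) {
    stop("dissimilarity matrix must be symmetric, nonnegative, zero-diagonal")
  }
  if (n < 3) stop("need at least 3 objects for 2-D MDS")
  denom <- sum(dissim^2) # over full matrix; consistent numerator below
  stress1 <- function(x) {
    d <- as.matrix(stats::dist(x))
    sqrt(sum((dissim - d)^2) / denom)
  }
  run <- function(x) {
    trace <- numeric(0)
    s_old <- stress1(x)
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(x))
      ratio <- ifelse(d > 0, dissim / d, 0)
      b <- -ratio
      diag(b) <- 0
      diag(b) <- -rowSums(b)
      x <- (b %*% x) / n  # Guttman transform (unit weights)
      s_new <- stress1(x)
      trace <- c(trace, s_new)
      if (s_old - s_new < tol * s_old) break
      s_old <- s_new
    }
    list(points = x, stress = stress1(x), trace = trace)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      x0 <- matrix(stats::rnorm(n * 2), n, 2) * max(dissim)
      fit <- run(x0)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  best$points <- scale(best$points, scale = FALSE)
  dimnames(best$points) <- list(rownames(dissim), c("dim1", "dim2"))
  best
}

#' Speech/nonspeech separability t score per region
#'
#' For each site in the region, computes the two-sample t statistic of the
#' sound-mean responses, speech versus nonspeech (pooled-variance by
#' default, Welch optionally), then aggregates sites into a region mean
#' with its standard error — the per-region separability score.
#'
#' @param srm a [sound_response_matrix()]
#' @param region region label; `NULL` uses all sites
#' @param var_equal pooled-variance t if `TRUE` (default)
#' @return list: `t_sites` (per-site t), `mean_t`, `se_t`, `n_sites`
#' @export
separability_tscore <- function(srm, region = NULL, var_equal = TRUE) {
  stopifnot(inherits(srm, "sound_response_matrix"))
  cols <- if (is.null(region)) seq_along(srm$region) else {
    which(srm$region == region)
  }
  if (length(cols) == 0) stop("no sites in region: ", region)
  sp <- srm$category == "speech"
  if (sum(sp) < 2 || sum(!sp) < 2) {
    stop("need at least 2 sounds per category")
  }
  t_sites <- vapply(cols, function(j) {
    stats::t.test(srm$means[sp, j], srm$means[!sp, j],
                  var.equal = var_equal)$statistic
  }, numeric(1))
  list(t_sites = unname(t_sites),
       mean_t = mean(t_sites),
       se_t = stats::sd(t_sites) / sqrt(length(t_sites)),
       n_sites = length(cols))
}

#' Category-cluster separation ratio of an MDS configuration
#'
#' Between-centroid distance divided by the mean within-category spread —
#' the quantitative form of "overlapping versus separated clusters" in an
#' MDS plot.
#'
#' @param points n x 2 coordinates
#' @param category per-point labels in `{speech, nonspeech}`
#' @return nonnegative scalar
#' @export
cluster_separation <- function(points, category) {
  stopifnot(nrow(points) == length(category))
  sp <- category == "speech"
  c_sp <- colMeans(points[sp, , drop = FALSE])
  c_ns <- colMeans(points[!sp, , drop = FALSE])
  between <- sqrt(sum((c_sp - c_ns)^2))
  spread <- function(x, ctr) {
    mean(sqrt(rowSums(sweep(x, 2, ctr)^2)))
  }
  within <- mean(c(spread(points[sp, , drop = FALSE], c_sp),
                   spread(points[!sp, , drop = FALSE], c_ns)))
  between / within
}
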